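#' One-sided Fisher exact test for cfDNA enrichment at one site
#'
#' Tests whether the alternate-allele proportion in cell-free DNA exceeds
#' that of the matched leukocyte control, via the exact hypergeometric tail
#' (equivalent to Fisher's exact test with the "greater" alternative).
#' Rescue asks only whether the tissue mutation is present in plasma, hence
#' the one-sided alternative.
#'
#' @param cf_alt,cf_ref alt/ref read counts in cfDNA (vectorized).
#' @param ctrl_alt,ctrl_ref alt/ref read counts in the control sample.
#' @return p-values in (0, 1]. An all-zero table yields p = 1 with a
#'   warning.
#' @export
fisher_site_test <- function(cf_alt, cf_ref, ctrl_alt, ctrl_ref) {
  if (any(c(cf_alt, cf_ref, ctrl_alt, ctrl_ref) < 0))
    stop("counts must be non-negative")
  n_tot <- cf_alt + cf_ref + ctrl_alt + ctrl_ref
  if (any(n_tot == 0)) warning("all-zero 2x2 table; p set to 1")
  k <- cf_alt + ctrl_alt          # total alt reads (margin)
  n1 <- cf_alt + cf_ref           # cfDNA depth (margin)
  # P(X >= cf_alt) for X ~ Hypergeom(k alt among n_tot, draw n1)
  p <- stats::phyper(cf_alt - 1, k, n_tot - k, n1, lower.tail = FALSE)
  p[n_tot == 0] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' @param p_values numeric vector in (0, 1].
#' @return q-values, attached to the same positions as the inputs (order
#'   invariant), monotone transform of the p-values, each at least its p.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Rescue configuration
#'
#' @param max_q maximum BH q-value (default 0.1).
#' @param min_vaf_ratio required cfDNA/control VAF ratio (default 2).
#' @param min_alt_reads minimum cfDNA alt reads (default 4).
#' @return object of class `rescue_config`.
#' @export
rescue_config <- function(max_q = 0.1, min_vaf_ratio = 2, min_alt_reads = 4L) {
  structure(list(max_q = max_q, min_vaf_ratio = min_vaf_ratio,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "rescue_config")
}

#' Tumor-informed plasma rescue of tissue mutations
#'
#' For each somatic mutation found in a patient's tissue, decides whether
#' it is detectable in the matched plasma sample from pileup counts. A site
#' is detected iff (1) cfDNA VAF >= `min_vaf_ratio` x control VAF, (2) the
#' BH q-value of the one-sided Fisher test is <= `max_q`, and (3) cfDNA alt
#' reads >= `min_alt_reads`. VAFs are computed from the pileup counts
#' (alt / (alt + ref)), not from any caller's VAF field. q-values are
#' adjusted within each patient's set of tissue-variant sites.
#'
#' @param tissue_variants data.frame with columns `patient_id` and `key`
#'   (one row per tissue mutation); further columns (gene, protein_change,
#'   ...) are carried through.
#' @param counts data.frame with columns `patient_id`, `key`, `cf_alt`,
#'   `cf_ref`, `ctrl_alt`, `ctrl_ref`.
#' @param cfg a [rescue_config()].
#' @return data.frame of class `rescue_results`: per site `cf_vaf`,
#'   `ctrl_vaf`, `p_value`, `q_value`, `detected` (logical; `NA` when the
#'   site has no counts and is reported untested), and `failed_rules`.
#' @export
rescue <- function(tissue_variants, counts, cfg = rescue_config()) {
  stopifnot(all(c("patient_id", "key") %in% names(tissue_variants)),
            all(c("patient_id", "key", "cf_alt", "cf_ref",
                  "ctrl_alt", "ctrl_ref") %in% names(counts)))
  res <- tissue_variants
  id <- paste(res$patient_id, res$key, sep = "\r")
  cid <- paste(counts$patient_id, counts$key, sep = "\r")
  if (anyDuplicated(cid)) stop("duplicate count rows for one site")
  m <- match(id, cid)
  res$cf_alt <- counts$cf_alt[m]; res$cf_ref <- counts$cf_ref[m]
  res$ctrl_alt <- counts$ctrl_alt[m]; res$ctrl_ref <- counts$ctrl_ref[m]
  tested <- !is.na(m)
  if (any(tested & (res$cf_alt + res$cf_ref) == 0))
    stop("tested site with zero cfDNA depth")
  res$cf_vaf <- res$cf_alt / (res$cf_alt + res$cf_ref)
  res$ctrl_vaf <- res$ctrl_alt / (res$ctrl_alt + res$ctrl_ref)
  res$p_value <- NA_real_
  res$p_value[tested] <- fisher_site_test(res$cf_alt[tested], res$cf_ref[tested],
                                          res$ctrl_alt[tested], res$ctrl_ref[tested])
  res$q_value <- NA_real_
  for (pt in unique(res$patient_id)) {
    sel <- tested & res$patient_id == pt
    res$q_value[sel] <- bh_adjust(res$p_value[sel])
  }
  fail_q <- res$q_value > cfg$max_q
  fail_ratio <- res$cf_vaf < cfg$min_vaf_ratio * res$ctrl_vaf
  fail_alt <- res$cf_alt < cfg$min_alt_reads
  res$detected <- ifelse(tested, !fail_q & !fail_ratio & !fail_alt, NA)
  res$failed_rules <- ifelse(
    !tested, "untested",
    trimws(paste(ifelse(fail_q, "max_q", ""),
                 ifelse(fail_ratio, "vaf_ratio", ""),
                 ifelse(fail_alt, "min_alt_reads", ""))))
  res$failed_rules <- gsub(" +", ";", res$failed_rules)
  class(res) <- unique(c("rescue_results", class(res)))
  res
}

#' Cohort-level plasma detection summary
#'
#' Aggregates per-patient rescue results into the cohort detection rate
#' (patients with at least one plasma-detected tissue mutation, over all
#' patients), the detected-mutation table, and the VAF range.
#'
#' @param detections data.frame of detected mutations with columns
#'   `patient_id`, `gene`, and optionally `protein_change`,
#'   `variant_class`, `vaf` (cfDNA VAF, fraction or percent as supplied).
#'   Typically `subset(rescue(...), detected)` or a curated table.
#' @param n_patients cohort size (> 0).
#' @return list: `n_patients`, `n_positive_patients`, `detection_rate`
#'   (fraction), `detection_rate_pct`, `n_mutations`, `vaf_range`, and
#'   `mutation_table` with a per-(gene, protein_change) plasma frequency
#'   (% of the cohort in which that mutation was detected).
#' @export
cohort_detection_summary <- function(detections, n_patients) {
  if (n_patients <= 0) stop("n_patients must be positive")
  if (nrow(detections) == 0)
    return(list(n_patients = n_patients, n_positive_patients = 0L,
                detection_rate = 0, detection_rate_pct = 0,
                n_mutations = 0L, vaf_range = c(NA_real_, NA_real_),
                mutation_table = detections))
  pos <- unique(detections$patient_id)
  pc <- if ("protein_change" %in% names(detections))
    ifelse(is.na(detections$protein_change), "/", detections$protein_change)
  else rep("/", nrow(detections))
  keyv <- paste(detections$gene, pc, sep = "\r")
  tab <- do.call(rbind, lapply(split(seq_len(nrow(detections)), keyv),
    function(idx) {
      d <- detections[idx, , drop = FALSE]
      data.frame(gene = d$gene[1], protein_change = pc[idx][1],
                 n_patients_detected = length(unique(d$patient_id)),
                 frequency_pct = round(100 * length(unique(d$patient_id)) /
                                         n_patients, 1),
                 patients = paste(sort(unique(d$patient_id)), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  rownames(tab) <- NULL
  vafs <- if ("vaf" %in% names(detections)) range(detections$vaf)
          else c(NA_real_, NA_real_)
  list(n_patients = n_patients,
       n_positive_patients = length(pos),
       detection_rate = length(pos) / n_patients,
       detection_rate_pct = round(100 * length(pos) / n_patients, 1),
       n_mutations = nrow(detections),
       vaf_range = vafs,
       mutation_table = tab[order(-tab$frequency_pct, tab$gene), ])
}
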