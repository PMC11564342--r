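#' Filter configuration for somatic consensus and quality rules
#'
#' Defaults follow the study protocol this pipeline implements: population
#' allele frequency (1000 Genomes / ExAC) at most 0.01, site mappability at
#' least 0.75, at least 100 bp between adjacent mutations of one sample,
#' tissue variants supported by at least two callers, and plasma variants
#' additionally requiring matched-normal VAF of zero and, when seen by a
#' single caller, VAF at least 0.05.
#'
#' @param max_pop_af maximum population AF (either database) to keep.
#' @param min_mappability minimum per-site mappability annotation.
#' @param min_pair_distance minimum distance (bp) between adjacent
#'   mutations in one patient+sample; every member of a closer cluster is
#'   removed (clusters are treated as alignment artifacts).
#' @param min_callers_tissue caller-consensus threshold for tissue.
#' @param plasma_single_caller_min_vaf VAF floor rescuing single-caller
#'   plasma variants.
#' @param require_normal_vaf_zero_plasma demand matched-normal VAF == 0 for
#'   plasma variants.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(max_pop_af = 0.01,
                          min_mappability = 0.75,
                          min_pair_distance = 100L,
                          min_callers_tissue = 2L,
                          plasma_single_caller_min_vaf = 0.05,
                          require_normal_vaf_zero_plasma = TRUE) {
  stopifnot(max_pop_af >= 0, max_pop_af <= 1,
            min_mappability >= 0, min_mappability <= 1,
            min_pair_distance >= 0,
            min_callers_tissue >= 1,
            plasma_single_caller_min_vaf >= 0,
            plasma_single_caller_min_vaf <= 1,
            is.logical(require_normal_vaf_zero_plasma))
  structure(list(max_pop_af = max_pop_af,
                 min_mappability = min_mappability,
                 min_pair_distance = as.integer(min_pair_distance),
                 min_callers_tissue = as.integer(min_callers_tissue),
                 plasma_single_caller_min_vaf = plasma_single_caller_min_vaf,
                 require_normal_vaf_zero_plasma = require_normal_vaf_zero_plasma),
            class = "filter_config")
}

.filter_report <- function(n_input, kept, removed) {
  counts <- if (nrow(removed)) table(unlist(strsplit(removed$rules, ";")))
            else table(character(0))
  structure(list(n_input = n_input, n_kept = nrow(kept),
                 n_removed = nrow(removed), removed = removed,
                 counts = counts),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report:", x$n_input, "in,", x$n_kept, "kept,",
      x$n_removed, "removed\n")
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Merge multi-caller calls into consensus variants
#'
#' Groups calls by patient, sample type and normalized variant key, then
#' applies the consensus rule. Tissue: keep keys reported by at least
#' `min_callers_tissue` distinct callers. Plasma: keep keys whose
#' matched-normal VAF is zero and that are either reported by two or more
#' callers or have VAF of at least `plasma_single_caller_min_vaf`. The
#' merged record takes VAF/depth from the caller with the highest depth.
#'
#' @param calls `somatic_calls` data.frame carrying a `key` column (see
#'   [normalize_calls()]). Plasma mode requires a `normal_vaf` column.
#' @param mode `"tissue"` or `"plasma"`.
#' @param cfg a [filter_config()].
#' @return list with `variants` (one merged row per kept key, plus
#'   `n_callers` and `callers` columns) and `report` (a `filter_report`).
#' @export
consensus_merge <- function(calls, mode = c("tissue", "plasma"),
                            cfg = filter_config()) {
  mode <- match.arg(mode)
  if (!("key" %in% names(calls)))
    stop("calls must carry a 'key' column; run normalize_calls() first")
  if (mode == "plasma" && cfg$require_normal_vaf_zero_plasma &&
      (!("normal_vaf" %in% names(calls)) || anyNA(calls$normal_vaf)))
    stop("plasma mode requires a matched-normal VAF ('normal_vaf') per variant")
  grp <- split(seq_len(nrow(calls)),
               paste(calls$patient_id, calls$sample_type, calls$key, sep = "\r"))
  rows <- lapply(grp, function(idx) {
    g <- calls[idx, , drop = FALSE]
    rep <- g[which.max(ifelse(is.na(g$depth), -1L, g$depth)), , drop = FALSE]
    rep$n_callers <- length(unique(g$caller))
    rep$callers <- paste(sort(unique(g$caller)), collapse = ",")
    rep
  })
  merged <- do.call(rbind, rows)
  rownames(merged) <- NULL
  rules <- character(nrow(merged))
  if (mode == "tissue") {
    fail <- merged$n_callers < cfg$min_callers_tissue
    rules[fail] <- "consensus_min_callers"
  } else {
    if (cfg$require_normal_vaf_zero_plasma) {
      bad_normal <- merged$normal_vaf != 0
      rules[bad_normal] <- "plasma_normal_vaf"
    } else bad_normal <- rep(FALSE, nrow(merged))
    single_low <- merged$n_callers < 2L &
      (is.na(merged$vaf) | merged$vaf < cfg$plasma_single_caller_min_vaf)
    rules[single_low] <- ifelse(nzchar(rules[single_low]),
                                paste(rules[single_low],
                                      "plasma_single_caller_vaf", sep = ";"),
                                "plasma_single_caller_vaf")
    fail <- bad_normal | single_low
  }
  kept <- merged[!fail, , drop = FALSE]
  removed <- merged[fail, c("patient_id", "sample_type", "key"), drop = FALSE]
  removed$rules <- rules[fail]
  list(variants = kept,
       report = .filter_report(nrow(merged), kept, removed))
}

#' Apply annotation and proximity quality filters
#'
#' Removes variants with population AF above `max_pop_af` in either
#' database (a missing AF is treated as 0: absence from the database is
#' evidence of rarity, and each such record is noted in the report), with
#' mappability below `min_mappability`, or with any same-sample neighbor
#' closer than `min_pair_distance` bp (all members of a proximity cluster
#' are removed). Proximity is evaluated within one patient+sample_type.
#'
#' @param variants merged variant data.frame (one row per variant per
#'   patient+sample), as produced by [consensus_merge()].
#' @param cfg a [filter_config()].
#' @return list with `variants` (kept) and `report`.
#' @export
quality_filters <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  rules <- character(n)
  add_rule <- function(rules, idx, rule)
    ifelse(seq_along(rules) %in% idx & nzchar(rules),
           paste(rules, rule, sep = ";"),
           ifelse(seq_along(rules) %in% idx, rule, rules))
  af1 <- ifelse(is.na(variants$pop_af_1kg), 0, variants$pop_af_1kg)
  af2 <- ifelse(is.na(variants$pop_af_exac), 0, variants$pop_af_exac)
  n_af_missing <- sum(is.na(variants$pop_af_1kg) | is.na(variants$pop_af_exac))
  rules <- add_rule(rules, which(pmax(af1, af2) > cfg$max_pop_af), "population_af")
  rules <- add_rule(rules,
                    which(!is.na(variants$mappability) &
                            variants$mappability < cfg$min_mappability),
                    "mappability")
  # proximity clusters: chain same-sample neighbours closer than the cutoff
  for (idx in split(seq_len(n), paste(variants$patient_id,
                                      variants$sample_type,
                                      variants$chrom, sep = "\r"))) {
    o <- idx[order(variants$pos[idx])]
    if (length(o) < 2) next
    gap <- diff(variants$pos[o])
    close_pair <- gap < cfg$min_pair_distance
    in_cluster <- c(close_pair, FALSE) | c(FALSE, close_pair)
    rules <- add_rule(rules, o[in_cluster], "proximity")
  }
  fail <- nzchar(rules)
  kept <- variants[!fail, , drop = FALSE]
  removed <- variants[fail, c("patient_id", "sample_type", "key"), drop = FALSE]
  removed$rules <- rules[fail]
  rep <- .filter_report(n, kept, removed)
  rep$n_pop_af_missing <- n_af_missing
  list(variants = kept, report = rep)
}

#' Full somatic filter: consensus then quality rules
#'
#' @inheritParams consensus_merge
#' @return list with `variants`, `consensus_report`, `quality_report`.
#' @export
apply_filters <- function(calls, mode = c("tissue", "plasma"),
                          cfg = filter_config()) {
  mode <- match.arg(mode)
  cons <- consensus_merge(calls, mode, cfg)
  qual <- quality_filters(cons$variants, cfg)
  list(variants = qual$variants,
       consensus_report = cons$report,
       quality_report = qual$report)
}
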