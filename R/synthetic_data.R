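# Default per-gene mutation frequencies for the two tissue cohorts,
# shaped like the frequently-mutated-gene panel of a conventional-adenoma
# vs stage-I carcinoma comparison: WNT genes dominate the adenomas, TP53 /
# PIK3CA rise sharply in carcinoma.
.default_gene_freqs <- function() {
  f <- rbind(
    APC     = c(0.67, 0.56),
    KRAS    = c(0.39, 0.28),
    TP53    = c(0.09, 0.42),
    PIK3CA  = c(0.04, 0.14),
    CTNNB1  = c(0.11, 0.01),
    SOX9    = c(0.13, 0.08),
    LRP1B   = c(0.12, 0.06),
    ARID1A  = c(0.11, 0.08),
    AXIN2   = c(0.09, 0.05),
    FBXW7   = c(0.05, 0.12),
    NRAS    = c(0.01, 0.06),
    CNTNAP5 = c(0.02, 0.12),
    GATA6   = c(0.08, 0.03),
    REL     = c(0.06, 0.02),
    AMER1   = c(0.06, 0.02),
    ATM     = c(0.05, 0.09),
    ZNF717  = c(0.10, 0.01),
    KMT2C   = c(0.15, 0.10),
    KMT2D   = c(0.08, 0.10))
  colnames(f) <- c("CRA", "CRC")
  f
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the study conditions this pipeline targets: 85 adenoma and 78 stage-I
#' carcinoma patients on a 3.34 Mb panel; mean depths 1000x (tissue),
#' 1500x (plasma), 2000x (leukocyte control); plasma shedding VAFs in the
#' 0.92-2.97% band; subclonal window (0.1, 0.25). One master seed fans out
#' to per-generator streams so adding a generator never perturbs others'
#' draws.
#'
#' @param seed master seed.
#' @param n_cra,n_crc cohort sizes.
#' @param gene_freqs matrix of per-gene frequencies with columns `CRA`,
#'   `CRC` (informative genes).
#' @param n_noise_genes,noise_freq count and shared frequency of
#'   uninformative genes added to the matrix.
#' @param depth_tissue,depth_plasma,depth_control sequencing depths.
#' @param caller_sensitivity named per-caller detection probabilities.
#' @param shed_vaf_range range of plasma shedding VAFs for shed variants.
#' @param bg_error background per-base error rate for unshed plasma sites.
#' @param fmin,fmax subclonal VAF window for the neutrality generators.
#' @param panel_size_mb panel territory.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cra = 85L, n_crc = 78L,
                       gene_freqs = .default_gene_freqs(),
                       n_noise_genes = 200L, noise_freq = 0.05,
                       depth_tissue = 1000L, depth_plasma = 1500L,
                       depth_control = 2000L,
                       caller_sensitivity = c(varscan2 = 0.95,
                                              strelka = 0.90, gvc = 0.85),
                       shed_vaf_range = c(0.0092, 0.0297),
                       bg_error = 1e-4,
                       fmin = 0.1, fmax = 0.25,
                       panel_size_mb = 3.34) {
  stopifnot(all(gene_freqs >= 0 & gene_freqs <= 1),
            noise_freq >= 0, noise_freq <= 1,
            depth_tissue > 0, depth_plasma > 0, depth_control > 0)
  structure(as.list(environment()), class = "sim_config")
}

.streams <- c("cohort", "calls", "plasma", "segments", "vafs", "cds",
              "coding", "pipeline")

.stream_seed <- function(seed, stream) {
  idx <- match(stream, .streams)
  if (is.na(idx)) stop("unknown stream: ", stream)
  as.integer((as.numeric(seed) * 977L + idx * 7919L) %% 2147483629)
}

#' Simulate a binary gene-by-patient cohort matrix
#'
#' Each gene mutates independently per patient as a Bernoulli draw with the
#' cohort's configured frequency; noise genes share one frequency in both
#' cohorts. Empirical frequencies converge to the configured values as the
#' cohort grows.
#'
#' @param cfg a [sim_config()].
#' @return list: `gm` (a [gene_matrix()]), `truth` (informative gene names
#'   and the frequency matrix used).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(.stream_seed(cfg$seed, "cohort"))
  freqs <- cfg$gene_freqs
  noise <- matrix(cfg$noise_freq, nrow = cfg$n_noise_genes, ncol = 2,
                  dimnames = list(sprintf("NOISE%03d", seq_len(cfg$n_noise_genes)),
                                  colnames(freqs)))
  all_freq <- rbind(freqs, noise)
  pts <- c(sprintf("CRA%03d", seq_len(cfg$n_cra)),
           sprintf("CRC%03d", seq_len(cfg$n_crc)))
  cohort <- stats::setNames(rep(c("CRA", "CRC"), c(cfg$n_cra, cfg$n_crc)), pts)
  mat <- matrix(0L, nrow(all_freq), length(pts),
                dimnames = list(rownames(all_freq), pts))
  for (g in rownames(all_freq)) {
    pr <- ifelse(cohort == "CRA", all_freq[g, "CRA"], all_freq[g, "CRC"])
    mat[g, ] <- stats::rbinom(length(pts), 1L, pr)
  }
  list(gm = gene_matrix(mat, cohort),
       truth = list(informative_genes = rownames(freqs), freqs = all_freq))
}

#' Simulate a planted-signal matrix for selection-recovery experiments
#'
#' Builds a cohort matrix in which `n_informative` genes carry clearly
#' detectable between-cohort signal — frequency ratios of 3-5x with the
#' rarer cohort at 4-12%, like the clearly differential genes of an
#' adenoma-vs-carcinoma panel (e.g. TP53 at 9 vs 42%) — in alternating
#' directions, plus `n_noise` genes mutated at one shared background
#' frequency in both cohorts. Ground truth is returned alongside.
#'
#' @param seed seed (fixes the frequency draw and the matrix).
#' @param n_informative,n_noise gene counts.
#' @param n_a,n_b cohort sizes (defaults 85 / 78).
#' @param noise_freq shared background frequency of noise genes.
#' @return list: `gm` (a [gene_matrix()] with cohorts `CRA`/`CRC`),
#'   `informative` (gene names), `freqs` (the frequency matrix used).
#' @export
simulate_planted_matrix <- function(seed = 1L, n_informative = 15L,
                                    n_noise = 200L, n_a = 85L, n_b = 78L,
                                    noise_freq = 0.05) {
  set.seed(.stream_seed(seed, "cohort"))
  lo <- stats::runif(n_informative, 0.04, 0.12)
  hi <- pmin(lo * stats::runif(n_informative, 3, 5), 0.6)
  toward_a <- seq_len(n_informative) %% 2 == 0
  fa <- ifelse(toward_a, hi, lo)
  fb <- ifelse(toward_a, lo, hi)
  genes <- c(sprintf("INF%02d", seq_len(n_informative)),
             sprintf("NOISE%03d", seq_len(n_noise)))
  pts <- c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b)))
  freqs <- rbind(cbind(CRA = fa, CRC = fb),
                 cbind(CRA = rep(noise_freq, n_noise),
                       CRC = rep(noise_freq, n_noise)))
  rownames(freqs) <- genes
  mat <- matrix(0L, length(genes), length(pts),
                dimnames = list(genes, pts))
  cohort <- stats::setNames(rep(c("CRA", "CRC"), c(n_a, n_b)), pts)
  for (i in seq_along(genes))
    mat[i, ] <- stats::rbinom(length(pts), 1L,
                              ifelse(cohort == "CRA", freqs[i, "CRA"],
                                     freqs[i, "CRC"]))
  list(gm = gene_matrix(mat, cohort),
       informative = genes[seq_len(n_informative)], freqs = freqs)
}

.random_snv <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate multi-caller somatic call sets with planted artifacts
#'
#' Plants `n_true` well-separated true somatic SNVs, each reported by
#' caller j with its configured sensitivity, then adds artifact classes
#' giving every filter rule positive and negative cases: common-SNP
#' contaminants (population AF 0.02), low-mappability sites (0.5), a
#' sub-100 bp proximity cluster, and single-caller false calls. Artifacts
#' live in genomic regions far from the true variants so cluster removal
#' never drags truth out.
#'
#' @param cfg a [sim_config()].
#' @param n_true number of true variants.
#' @param patient patient id.
#' @param sensitivities per-caller detection probabilities; the default
#'   `cfg$caller_sensitivity`. Set all to 1 for an exact-recovery fixture.
#' @param n_false_single single-caller false positives.
#' @return list: `calls` (a keyed `somatic_calls` table), `truth_keys`,
#'   `artifacts` (data.frame of key + planted type).
#' @export
simulate_multicaller_calls <- function(cfg = sim_config(), n_true = 20L,
                                       patient = "P1",
                                       sensitivities = cfg$caller_sensitivity,
                                       n_false_single = 4L) {
  set.seed(.stream_seed(cfg$seed, "calls"))
  callers <- names(sensitivities)
  mk_rows <- function(pos, ref, alt, vaf, caller, pop1 = NA, pope = NA,
                      mapq = 0.95) {
    depth <- cfg$depth_tissue
    data.frame(patient_id = patient, sample_type = "tissue", chrom = "chr1",
               pos = pos, ref = ref, alt = alt, caller = caller,
               vaf = round(vaf * depth) / depth, depth = depth,
               alt_reads = round(vaf * depth),
               pop_af_1kg = pop1, pop_af_exac = pope, mappability = mapq,
               gene = NA, variant_class = "missense", protein_change = NA,
               stringsAsFactors = FALSE)
  }
  # true variants, >= 500 bp apart
  tv <- .random_snv(n_true)
  tpos <- 10000L + seq_len(n_true) * 500L
  tvaf <- stats::runif(n_true, 0.1, 0.5)
  rows <- list()
  for (i in seq_len(n_true)) {
    det <- callers[stats::runif(length(callers)) <= sensitivities]
    for (cl in det)
      rows[[length(rows) + 1L]] <- mk_rows(tpos[i], tv$ref[i], tv$alt[i],
                                           tvaf[i], cl)
  }
  truth_keys <- variant_key("chr1", tpos, tv$ref, tv$alt)
  art <- list()
  plant <- function(pos, ref, alt, vaf, type, callers_used, ...) {
    for (cl in callers_used)
      rows[[length(rows) + 1L]] <<- mk_rows(pos, ref, alt, vaf, cl, ...)
    art[[length(art) + 1L]] <<- data.frame(
      key = variant_key("chr1", pos, ref, alt), type = type,
      stringsAsFactors = FALSE)
  }
  two <- callers[seq_len(min(2L, length(callers)))]
  # common-SNP contaminants: seen by two callers, removed by population_af
  sp <- .random_snv(2L)
  plant(200000L, sp$ref[1], sp$alt[1], 0.45, "population_af", two,
        pop1 = 0.02)
  plant(201000L, sp$ref[2], sp$alt[2], 0.30, "population_af", two,
        pope = 0.05)
  # low-mappability sites
  lm <- .random_snv(2L)
  plant(300000L, lm$ref[1], lm$alt[1], 0.25, "mappability", two, mapq = 0.5)
  plant(301000L, lm$ref[2], lm$alt[2], 0.20, "mappability", two, mapq = 0.6)
  # proximity cluster: three calls 40 bp apart, all to be removed
  cl3 <- .random_snv(3L)
  for (j in 1:3)
    plant(400000L + (j - 1L) * 40L, cl3$ref[j], cl3$alt[j], 0.15,
          "proximity", two)
  # single-caller false calls, removed by consensus
  fs <- .random_snv(n_false_single)
  for (j in seq_len(n_false_single))
    plant(500000L + j * 1000L, fs$ref[j], fs$alt[j], 0.08,
          "consensus_min_callers", callers[1L + (j %% length(callers))])
  calls <- somatic_calls(do.call(rbind, rows))
  calls <- normalize_calls(calls)  # SNVs: attaches keys
  list(calls = calls, truth_keys = truth_keys,
       artifacts = do.call(rbind, art))
}

#' Simulate plasma/control pileup counts for tissue mutations
#'
#' Shed variants draw cfDNA alt reads binomially at the configured plasma
#' depth from VAFs in the shedding band; unshed variants draw from the
#' background error rate. Control alt reads are 0 by construction unless
#' `ctrl_error > 0`.
#'
#' @param cfg a [sim_config()].
#' @param n_shed,n_unshed site counts.
#' @param patient patient id.
#' @param shed_vafs optional explicit shedding VAFs (length `n_shed`).
#' @param ctrl_error control-sample error rate (default 0).
#' @return list: `counts` (rescue-ready data.frame), `truth` (per-site
#'   `shed` flag and true VAF).
#' @export
simulate_plasma_counts <- function(cfg = sim_config(), n_shed = 10L,
                                   n_unshed = 10L, patient = "P1",
                                   shed_vafs = NULL, ctrl_error = 0) {
  set.seed(.stream_seed(cfg$seed, "plasma"))
  n <- n_shed + n_unshed
  snv <- .random_snv(n)
  keys <- variant_key("chr2", 1000L + seq_len(n) * 1000L, snv$ref, snv$alt)
  if (is.null(shed_vafs))
    shed_vafs <- stats::runif(n_shed, cfg$shed_vaf_range[1],
                              cfg$shed_vaf_range[2])
  true_vaf <- c(shed_vafs, rep(cfg$bg_error, n_unshed))
  shed <- rep(c(TRUE, FALSE), c(n_shed, n_unshed))
  cf_alt <- stats::rbinom(n, cfg$depth_plasma, true_vaf)
  ctrl_alt <- stats::rbinom(n, cfg$depth_control, ctrl_error)
  list(counts = data.frame(patient_id = patient, key = keys,
                           cf_alt = cf_alt,
                           cf_ref = cfg$depth_plasma - cf_alt,
                           ctrl_alt = ctrl_alt,
                           ctrl_ref = cfg$depth_control - ctrl_alt,
                           stringsAsFactors = FALSE),
       truth = data.frame(key = keys, shed = shed, true_vaf = true_vaf,
                          stringsAsFactors = FALSE))
}

#' Construct a copy-number segment plan with a target GII
#'
#' Lays `n_segments` equal-length segments along one synthetic genome and
#' marks `round(target_gii * n_segments)` of them aberrant (cycling gain /
#' loss / CN-LOH), so the realized GII equals the target within one
#' segment's resolution (1 / `n_segments`).
#'
#' @param target_gii desired genome instability index in [0, 1].
#' @param n_segments number of segments.
#' @param total_mb total segmented length in Mb.
#' @param sample sample id.
#' @return a [cn_segments()] data.frame.
#' @export
simulate_segments <- function(target_gii, n_segments = 20L, total_mb = 3000,
                              sample = "S1") {
  stopifnot(target_gii >= 0, target_gii <= 1, n_segments > 0)
  seg_len <- round(total_mb * 1e6 / n_segments)
  k <- round(target_gii * n_segments)
  states <- rep("neutral", n_segments)
  if (k > 0)
    states[seq_len(k)] <- rep(c("gain", "loss", "cnloh"), length.out = k)
  cn <- list(gain = c(3L, 1L), loss = c(1L, 0L), cnloh = c(2L, 0L),
             neutral = c(2L, 1L))
  start <- (seq_len(n_segments) - 1L) * seg_len
  cn_segments(data.frame(
    sample = sample, chrom = "chr1", start = start, end = start + seg_len,
    total_cn = vapply(states, function(s) cn[[s]][1], integer(1)),
    minor_cn = vapply(states, function(s) cn[[s]][2], integer(1)),
    state = states, stringsAsFactors = FALSE))
}

#' Simulate a neutrally evolving subclonal VAF spectrum
#'
#' True frequencies follow the density proportional to 1/f^2 on
#' (`fmin`, `fmax`) — the spectrum under neutral growth, for which the
#' cumulative count M(f) is proportional to 1/f - 1/fmax. With
#' `noiseless = TRUE` frequencies sit exactly on the model quantiles
#' (k/(n+1) survival levels), making the 1/f fit exact; otherwise binomial
#' read sampling at `depth` is applied.
#'
#' @param cfg a [sim_config()] (supplies window and seed stream).
#' @param n number of subclonal mutations.
#' @param depth read depth for binomial noise.
#' @param noiseless place frequencies exactly on the model.
#' @param seed optional seed overriding the config stream.
#' @return numeric vector of VAFs.
#' @export
simulate_neutral_vafs <- function(cfg = sim_config(), n = 1000L,
                                  depth = cfg$depth_tissue,
                                  noiseless = FALSE, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seed(cfg$seed, "vafs") else seed)
  a <- 1 / cfg$fmin - 1 / cfg$fmax
  q <- if (noiseless) seq_len(n) / (n + 1) else stats::runif(n)
  f <- 1 / (1 / cfg$fmax + q * a)   # survival-level q maps to frequency f
  if (noiseless) return(f)
  stats::rbinom(n, depth, f) / depth
}

#' Simulate a selected (non-neutral) VAF spectrum
#'
#' A neutral 1/f^2 tail plus one dominant subclonal cluster, which
#' violates the linear M(f) ~ 1/f shape.
#'
#' @inheritParams simulate_neutral_vafs
#' @param n_tail neutral tail mutations.
#' @param cluster_vaf,cluster_n location and size of the planted subclone.
#' @return numeric vector of VAFs.
#' @export
simulate_selected_vafs <- function(cfg = sim_config(), n_tail = 200L,
                                   cluster_vaf = 0.18, cluster_n = 300L,
                                   depth = cfg$depth_tissue, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seed(cfg$seed, "vafs") else seed)
  a <- 1 / cfg$fmin - 1 / cfg$fmax
  f <- 1 / (1 / cfg$fmax + stats::runif(n_tail) * a)
  f <- c(f, rep(cluster_vaf, cluster_n))
  stats::rbinom(length(f), depth, f) / depth
}

#' Simulate an in-frame CDS set
#'
#' Random coding sequences assembled from the 61 non-stop codons, so no
#' internal stops arise.
#'
#' @param n_genes number of genes.
#' @param n_codons codons per gene.
#' @param seed seed.
#' @return named character vector of CDS.
#' @export
simulate_cds <- function(n_genes = 100L, n_codons = 300L, seed = 1L) {
  set.seed(.stream_seed(seed, "cds"))
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  stats::setNames(
    vapply(seq_len(n_genes), function(i)
      paste(sample(ok, n_codons, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("gene%03d", seq_len(n_genes)))
}

#' Simulate coding mutations over an opportunity table
#'
#' Mutations are drawn from the opportunity-weighted substitution space
#' (uniform per-context base rates); nonsynonymous draws in gene g are
#' up-weighted by the selection coefficient `w[g]` (w = 1 neutral, w > 1
#' positive selection, w = 0 removes nonsynonymous mutations).
#'
#' @param opp an [build_opportunity_table()] result.
#' @param n number of mutations.
#' @param w scalar or named per-gene selection coefficient.
#' @param seed seed.
#' @param vafs optional VAFs attached to the output rows (recycled).
#' @return data.frame with `gene`, `context`, `class` (and `vaf` if
#'   supplied).
#' @export
simulate_coding_mutations <- function(opp, n = 2000L, w = 1, seed = 1L,
                                      vafs = NULL) {
  set.seed(.stream_seed(seed, "coding"))
  genes <- rownames(opp$N)
  wg <- if (length(w) == 1) stats::setNames(rep(w, length(genes)), genes)
        else w[genes]
  if (anyNA(wg)) stop("selection coefficients must cover every gene")
  cells <- rbind(
    data.frame(gene = rep(genes, ncol(opp$N)),
               context = rep(colnames(opp$N), each = length(genes)),
               class = "nonsynonymous",
               weight = as.vector(opp$N) * rep(wg, ncol(opp$N)),
               stringsAsFactors = FALSE),
    data.frame(gene = rep(genes, ncol(opp$S)),
               context = rep(colnames(opp$S), each = length(genes)),
               class = "synonymous",
               weight = as.vector(opp$S),
               stringsAsFactors = FALSE))
  cells <- cells[cells$weight > 0, , drop = FALSE]
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$weight)
  out <- cells[idx, c("gene", "context", "class")]
  rownames(out) <- NULL
  if (!is.null(vafs)) out$vaf <- rep_len(vafs, n)
  out
}
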