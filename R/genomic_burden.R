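#' Tumor mutational burden (mutations per megabase)
#'
#' TMB is the number of qualifying somatic mutations divided by the size of
#' the sequenced territory in Mb. The default panel size is 3.34 Mb (a
#' 451-gene cancer panel); the default numerator counts nonsynonymous
#' mutations (missense, nonsense, frameshift, splice) and is switchable to
#' all mutations.
#'
#' @param variants a somatic variant data.frame with a `variant_class`
#'   column, or a single non-negative count.
#' @param panel_size_mb sequenced territory in Mb (> 0).
#' @param numerator `"nonsynonymous"` or `"all"`.
#' @return mutations per Mb.
#' @export
compute_tmb <- function(variants, panel_size_mb = 3.34,
                        numerator = c("nonsynonymous", "all")) {
  numerator <- match.arg(numerator)
  if (panel_size_mb <= 0) stop("panel_size_mb must be positive")
  if (is.numeric(variants) && length(variants) == 1) {
    n <- variants
    if (n < 0) stop("negative mutation count")
  } else {
    if (numerator == "nonsynonymous") {
      if (!("variant_class" %in% names(variants)))
        stop("variants need a variant_class column for the nonsynonymous TMB")
      n <- sum(variants$variant_class %in%
                 c("missense", "nonsense", "frameshift", "splice"), na.rm = TRUE)
    } else n <- nrow(variants)
  }
  n / panel_size_mb
}

#' Classify an allele-specific copy-number segment
#'
#' Relative to the baseline ploidy: `gain` when total copy number exceeds
#' it, `loss` when below it, `cnloh` (copy-neutral loss of heterozygosity)
#' when total equals baseline with minor copy number 0, otherwise
#' `neutral`.
#'
#' @param total_cn,minor_cn integer copy numbers (vectorized).
#' @param baseline_ploidy baseline total copy number (default diploid, 2;
#'   pass the sample's rounded ploidy for aneuploid tissue).
#' @return character vector in `{gain, loss, cnloh, neutral}`.
#' @export
classify_segment <- function(total_cn, minor_cn, baseline_ploidy = 2L) {
  ifelse(total_cn > baseline_ploidy, "gain",
         ifelse(total_cn < baseline_ploidy, "loss",
                ifelse(minor_cn == 0L & baseline_ploidy > 0L, "cnloh",
                       "neutral")))
}

#' Genome instability index from copy-number segments
#'
#' GII is the fraction of the segmented genome affected by copy-number
#' gain, loss, or copy-neutral LOH. The denominator is the total segmented
#' length (not a fixed genome size), so targeted data are handled
#' gracefully.
#'
#' @param segments a [cn_segments()] data.frame (single sample;
#'   non-overlapping per chromosome).
#' @param baseline_ploidy see [classify_segment()].
#' @return list with `gii` and `fractions` (named: gain, loss, cnloh,
#'   neutral; summing to 1).
#' @export
compute_gii <- function(segments, baseline_ploidy = 2L) {
  len <- segments$end - segments$start
  total <- sum(len)
  if (total <= 0) stop("zero total segmented length")
  cls <- classify_segment(segments$total_cn, segments$minor_cn, baseline_ploidy)
  frac <- vapply(c("gain", "loss", "cnloh", "neutral"),
                 function(k) sum(len[cls == k]) / total, numeric(1))
  list(gii = unname(frac["gain"] + frac["loss"] + frac["cnloh"]),
       fractions = frac)
}

#' Per-sample burden summary (TMB + GII)
#'
#' @param variants per-sample variant data.frame (may be `NULL`).
#' @param segments per-sample [cn_segments()] (may be `NULL`).
#' @inheritParams compute_tmb
#' @inheritParams compute_gii
#' @return one-row data.frame with `tmb`, `gii` and class fractions.
#' @export
sample_burden <- function(variants = NULL, segments = NULL,
                          panel_size_mb = 3.34,
                          numerator = "nonsynonymous",
                          baseline_ploidy = 2L) {
  tmb <- if (is.null(variants)) NA_real_
         else compute_tmb(variants, panel_size_mb, numerator)
  if (is.null(segments))
    return(data.frame(tmb = tmb, gii = NA_real_, gain = NA_real_,
                      loss = NA_real_, cnloh = NA_real_, neutral = NA_real_))
  g <- compute_gii(segments, baseline_ploidy)
  data.frame(tmb = tmb, gii = g$gii, gain = g$fractions[["gain"]],
             loss = g$fractions[["loss"]], cnloh = g$fractions[["cnloh"]],
             neutral = g$fractions[["neutral"]])
}
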