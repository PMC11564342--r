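#' Partition a VAF spectrum into clonal and subclonal mutations
#'
#' Mutations with VAF >= `cutoff` are clonal (the boundary value is
#' clonal); the rest are subclonal. The default cutoff of 0.25 follows the
#' overall VAF distribution of diploid panel data (a heterozygous clonal
#' mutation in a pure tumor sits at VAF 0.5; admixture halves it).
#'
#' @param vafs numeric vector of variant allele fractions in (0, 1].
#' @param cutoff clonality boundary.
#' @return list with `clonal` and `subclonal` numeric vectors.
#' @export
split_clonality <- function(vafs, cutoff = 0.25) {
  stopifnot(all(vafs > 0 & vafs <= 1))
  list(clonal = vafs[vafs >= cutoff], subclonal = vafs[vafs < cutoff])
}

#' 1/f neutral-evolution test on the subclonal VAF spectrum
#'
#' Under neutral tumor growth the cumulative number of subclonal mutations
#' with frequency at least f grows linearly in 1/f: M(f) = (mu/beta)(1/f -
#' 1/fmax). The test takes the mutations with VAF strictly inside
#' (`fmin`, `fmax`), evaluates M(f) at each observed VAF (ties collapsed),
#' and fits M(f) against x = 1/f - 1/fmax by least squares through the
#' origin. The sample is classified neutral when the fit's R-squared is at
#' least `r2_threshold` (default 0.98, the conventional classification
#' cutoff). R-squared is computed against the mean of M, so it can be
#' negative; it is clipped at 0.
#'
#' @param vafs numeric VAF vector for one sample.
#' @param fmin,fmax subclonal window (open interval).
#' @param r2_threshold neutrality classification threshold on R-squared.
#' @param n_min minimum number of subclonal mutations for an evaluable fit
#'   (default 12; below it the result is flagged not evaluable, neither
#'   neutral nor non-neutral).
#' @return object of class `neutrality_fit`: `r_squared`, `mu_per_beta`
#'   (fitted slope), `n_subclonal`, `evaluable`, `is_neutral` (`NA` when
#'   not evaluable), and the fitted points (`f`, `x`, `M`).
#' @export
neutrality_test <- function(vafs, fmin = 0.1, fmax = 0.25,
                            r2_threshold = 0.98, n_min = 12L) {
  stopifnot(fmin > 0, fmax > fmin)
  sub <- vafs[vafs > fmin & vafs < fmax]
  n_sub <- length(sub)
  out <- structure(list(r_squared = NA_real_, mu_per_beta = NA_real_,
                        n_subclonal = n_sub, evaluable = FALSE,
                        is_neutral = NA, r2_threshold = r2_threshold,
                        fmin = fmin, fmax = fmax,
                        f = numeric(0), x = numeric(0), M = numeric(0)),
                   class = "neutrality_fit")
  if (n_sub < n_min) return(out)
  f <- sort(unique(sub), decreasing = TRUE)
  M <- vapply(f, function(fi) sum(sub >= fi), numeric(1))
  x <- 1 / f - 1 / fmax
  slope <- sum(x * M) / sum(x * x)
  ss_res <- sum((M - slope * x)^2)
  ss_tot <- sum((M - mean(M))^2)
  r2 <- if (ss_tot == 0) 0 else max(0, 1 - ss_res / ss_tot)
  out$r_squared <- r2
  out$mu_per_beta <- slope
  out$evaluable <- TRUE
  out$is_neutral <- r2 >= r2_threshold
  out$f <- f; out$x <- x; out$M <- M
  out
}

#' @export
print.neutrality_fit <- function(x, ...) {
  if (!x$evaluable) {
    cat("neutrality fit: not evaluable (", x$n_subclonal,
        " subclonal mutations in (", x$fmin, ", ", x$fmax, "))\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "neutrality fit: R^2 = %.4f (threshold %.2f) -> %s\n  slope mu/beta = %.2f over %d subclonal mutations in (%g, %g)\n",
    x$r_squared, x$r2_threshold,
    if (x$is_neutral) "neutral" else "non-neutral",
    x$mu_per_beta, x$n_subclonal, x$fmin, x$fmax))
  invisible(x)
}

#' Shared-origin call for multiple lesions of one patient
#'
#' Two or more synchronous adenomas either developed independently or share
#' a common ancestral clone. The call is `shared-ancestor` iff at least one
#' identical normalized variant key is present in two or more lesions;
#' otherwise `independent`.
#'
#' @param lesion_sets named list (>= 2 elements) of character vectors of
#'   variant keys, one per lesion.
#' @return list with `origin` (`"independent"` or `"shared-ancestor"`),
#'   `shared_keys`, and `pairs` (data.frame of lesion pairs with >= 1
#'   shared key).
#' @export
shared_mutation_origin <- function(lesion_sets) {
  if (length(lesion_sets) < 2) stop("need at least two lesions")
  if (is.null(names(lesion_sets)))
    names(lesion_sets) <- paste0("lesion", seq_along(lesion_sets))
  combs <- utils::combn(names(lesion_sets), 2, simplify = FALSE)
  pairs <- do.call(rbind, lapply(combs, function(pr) {
    sh <- intersect(lesion_sets[[pr[1]]], lesion_sets[[pr[2]]])
    if (!length(sh)) return(NULL)
    data.frame(lesion_a = pr[1], lesion_b = pr[2], n_shared = length(sh),
               shared = paste(sh, collapse = ","), stringsAsFactors = FALSE)
  }))
  shared_keys <- unique(unlist(lapply(combs, function(pr)
    intersect(lesion_sets[[pr[1]]], lesion_sets[[pr[2]]]))))
  list(origin = if (length(shared_keys)) "shared-ancestor" else "independent",
       shared_keys = shared_keys,
       pairs = if (is.null(pairs)) data.frame() else pairs)
}
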