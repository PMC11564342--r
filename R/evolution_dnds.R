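# --- trinucleotide context machinery -------------------------------------

.bases <- c("A", "C", "G", "T")

.comp <- function(b) chartr("ACGT", "TGCA", b)

# Strand-collapse a (trinucleotide, alt) pair so the mutated base is a
# pyrimidine; labels look like "ACA>T". Vectorized.
.collapse_context <- function(tri, alt) {
  center <- substr(tri, 2, 2)
  pur <- center %in% c("A", "G")
  rc_tri <- paste0(.comp(substr(tri, 3, 3)), .comp(center), .comp(substr(tri, 1, 1)))
  out_tri <- ifelse(pur, rc_tri, tri)
  out_alt <- ifelse(pur, .comp(alt), alt)
  paste0(out_tri, ">", out_alt)
}

# The 96 strand-collapsed context labels (32 pyrimidine-centered
# trinucleotides x 3 alternate bases).
.all_contexts <- function() {
  ctx <- character(0)
  for (c1 in .bases) for (c0 in c("C", "T")) for (c2 in .bases)
    for (a in setdiff(.bases, c0))
      ctx <- c(ctx, paste0(c1, c0, c2, ">", a))
  sort(ctx)
}

# lookup[codon, pos, alt] -> TRUE if the substitution is synonymous
.syn_lookup <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    arr <- array(NA, dim = c(64, 3, 4),
                 dimnames = list(codons, c("1", "2", "3"), .bases))
    for (cd in codons) for (j in 1:3) for (b in .bases) {
      if (substr(cd, j, j) == b) next
      mut <- cd
      substr(mut, j, j) <- b
      arr[cd, j, b] <- unname(gc[mut] == gc[cd])
    }
    tbl <<- arr
    tbl
  }
})

#' Build the per-gene mutational opportunity table
#'
#' For every coding position and every possible single-base substitution,
#' tallies whether the change is synonymous or nonsynonymous under the
#' standard genetic code, stratified by the 96 strand-collapsed
#' trinucleotide contexts. These opportunity counts are the denominators of
#' the dN/dS model: context-specific mutation rates are estimated from
#' synonymous counts over synonymous opportunities and shared across genes.
#'
#' The first and last base of each CDS take an `A` padding flank for their
#' context, so per-gene totals are exactly 3 x coding length.
#'
#' @param cds named character vector (or `Biostrings::DNAStringSet`) of
#'   in-frame coding sequences, lengths divisible by 3. A terminal stop
#'   codon is allowed; an internal stop raises an error naming the gene.
#' @return object of class `opportunity_table`: matrices `N` and `S`
#'   (genes x 96 contexts) and `lengths` (coding lengths in bp).
#' @export
build_opportunity_table <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  stopifnot(is.character(cds), !is.null(names(cds)))
  contexts <- .all_contexts()
  lk <- .syn_lookup()
  gc <- Biostrings::GENETIC_CODE
  N <- S <- matrix(0, nrow = length(cds), ncol = length(contexts),
                   dimnames = list(names(cds), contexts))
  for (g in names(cds)) {
    s <- toupper(cds[[g]])
    L <- nchar(s)
    if (L %% 3 != 0) stop("CDS length of ", g, " not divisible by 3")
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% .bases)) stop("non-ACGT base in CDS of ", g)
    codons <- substring(s, seq(1, L, 3), seq(3, L, 3))
    aa <- unname(gc[codons])
    if (any(aa[-length(aa)] == "*"))
      stop("internal stop codon in CDS of ", g)
    codon_per_pos <- rep(codons, each = 3)
    pos_in_codon <- rep(1:3, length(codons))
    padded <- c("A", ch, "A")
    tri <- paste0(padded[seq_len(L)], ch, padded[seq_len(L) + 2L])
    # three alternate bases per position
    alt_mat <- vapply(.bases, function(b) rep(b, L), character(L))
    keep <- alt_mat != ch  # L x 4, exactly 3 TRUE per row
    pos_idx <- rep(seq_len(L), 4)[keep]
    alts <- alt_mat[keep]
    syn <- lk[cbind(codon_per_pos[pos_idx],
                    as.character(pos_in_codon[pos_idx]), alts)]
    ctx <- .collapse_context(tri[pos_idx], alts)
    ts <- table(factor(ctx[syn], levels = contexts))
    tn <- table(factor(ctx[!syn], levels = contexts))
    S[g, ] <- as.numeric(ts)
    N[g, ] <- as.numeric(tn)
  }
  structure(list(N = N, S = S,
                 lengths = vapply(cds, nchar, numeric(1))),
            class = "opportunity_table")
}

.check_mutations <- function(mutations, opp) {
  stopifnot(all(c("gene", "context", "class") %in% names(mutations)))
  if (!all(mutations$class %in% c("synonymous", "nonsynonymous")))
    stop("mutation class must be synonymous or nonsynonymous")
  bad <- setdiff(unique(mutations$context), colnames(opp$N))
  if (length(bad)) stop("unknown context(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Core estimator. Contexts with zero synonymous opportunity have an
# unidentifiable rate; they are excluded from both the observed
# nonsynonymous count and the expectation (otherwise dN/dS is biased
# upward by mutations whose expectation cannot be estimated).
.dnds_core <- function(n_syn_by_ctx, n_nonsyn_by_ctx, opp_S, opp_N) {
  if (sum(n_syn_by_ctx) == 0)
    stop("zero synonymous mutations: rates unidentifiable")
  if (any(n_syn_by_ctx > 0 & opp_S == 0))
    stop("synonymous mutation in a context with zero synonymous opportunity")
  identifiable <- opp_S > 0
  rate <- ifelse(identifiable, n_syn_by_ctx / opp_S, 0)
  expected_n <- sum(rate[identifiable] * opp_N[identifiable])
  n_obs <- sum(n_nonsyn_by_ctx[identifiable])
  n_dropped <- sum(n_nonsyn_by_ctx[!identifiable])
  dnds <- n_obs / expected_n
  # delta-method CI on log(dN/dS): the numerator is Poisson and the
  # expectation itself is estimated from synonymous counts, so both
  # sampling sources enter the variance (a Poisson-only CI undercovers
  # whenever synonymous counts are modest)
  var_exp <- sum(n_syn_by_ctx[identifiable] *
                   (opp_N[identifiable] / opp_S[identifiable])^2)
  se_log <- sqrt(1 / max(n_obs, 1) + var_exp / expected_n^2)
  ci <- if (n_obs == 0)
    c(0, stats::qgamma(0.975, 1) / expected_n * exp(1.96 * se_log))
  else dnds * exp(c(-1.96, 1.96) * se_log)
  list(dnds = dnds, ci_low = ci[1], ci_high = ci[2],
       observed_n = n_obs, expected_n = expected_n, rate = rate,
       identifiable = identifiable, n_dropped = n_dropped)
}

#' Global dN/dS selection estimate
#'
#' Context-specific neutral mutation rates are estimated from synonymous
#' counts divided by synonymous opportunities (summed over genes); the
#' expected nonsynonymous count is the rate-weighted sum of nonsynonymous
#' opportunities, and dN/dS is observed over expected nonsynonymous
#' mutations. The 95% CI comes from the exact Poisson interval of the
#' observed count. dN/dS > 1 indicates positive selection (mutations
#' promoting growth), < 1 negative selection.
#'
#' @param mutations data.frame with columns `gene`, `context` (collapsed
#'   trinucleotide label, e.g. `"ACA>T"`), `class` (`synonymous` /
#'   `nonsynonymous`).
#' @param opp an [build_opportunity_table()] result.
#' @param scope label stored in the result (`"global"`, `"clonal"`,
#'   `"subclonal"`).
#' @return object of class `dnds_result`.
#' @export
global_dnds <- function(mutations, opp, scope = "global") {
  .check_mutations(mutations, opp)
  contexts <- colnames(opp$N)
  syn <- mutations$class == "synonymous"
  s_ctx <- table(factor(mutations$context[syn], levels = contexts))
  n_ctx <- table(factor(mutations$context[!syn], levels = contexts))
  core <- .dnds_core(as.numeric(s_ctx), as.numeric(n_ctx),
                     colSums(opp$S), colSums(opp$N))
  structure(c(list(scope = scope, gene = NA_character_,
                   n_syn = sum(syn)), core[c(1:5, 8)]),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS (%s%s): %.3f [95%% CI %.3f, %.3f]  (observed N = %d, expected N = %.2f, S = %d)\n",
              x$scope, if (!is.na(x$gene)) paste0(":", x$gene) else "",
              x$dnds, x$ci_low, x$ci_high, x$observed_n, x$expected_n,
              x$n_syn))
  invisible(x)
}

#' Per-gene dN/dS with a Poisson excess test
#'
#' Rates are estimated cohort-wide (as in [global_dnds()]); each gene's
#' observed nonsynonymous count is tested against its expectation with a
#' one-sided Poisson test. Genes with dN/dS > 1 and p <= `alpha` are
#' flagged positively selected.
#'
#' @inheritParams global_dnds
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame: per gene `dnds`, `ci_low`, `ci_high`,
#'   `observed_n`, `expected_n`, `p_value`, `selected`.
#' @export
gene_dnds <- function(mutations, opp, alpha = 0.05) {
  .check_mutations(mutations, opp)
  contexts <- colnames(opp$N)
  syn <- mutations$class == "synonymous"
  if (!any(syn)) stop("zero synonymous mutations: rates unidentifiable")
  s_ctx <- as.numeric(table(factor(mutations$context[syn], levels = contexts)))
  opp_S <- colSums(opp$S)
  identifiable <- opp_S > 0
  rate <- ifelse(identifiable, s_ctx / opp_S, 0)
  ok_ctx <- contexts[identifiable]
  genes <- unique(mutations$gene)
  known <- genes %in% rownames(opp$N)
  if (any(!known)) {
    warning("genes absent from opportunity table skipped: ",
            paste(genes[!known], collapse = ", "))
    genes <- genes[known]
  }
  rows <- lapply(genes, function(g) {
    obs <- sum(mutations$gene == g & !syn & mutations$context %in% ok_ctx)
    expn <- sum(rate[identifiable] * opp$N[g, identifiable])
    if (expn <= 0)
      return(data.frame(gene = g, dnds = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, observed_n = obs,
                        expected_n = expn, p_value = NA_real_,
                        selected = FALSE))
    p <- stats::poisson.test(obs, T = expn, r = 1,
                             alternative = "greater")$p.value
    data.frame(gene = g, dnds = obs / expn,
               ci_low = if (obs == 0) 0 else stats::qgamma(0.025, obs) / expn,
               ci_high = stats::qgamma(0.975, obs + 1) / expn,
               observed_n = obs, expected_n = expn, p_value = p,
               selected = obs / expn > 1 & p <= alpha)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), ]
}

#' dN/dS split by clonality
#'
#' Runs [global_dnds()] on the clonal (VAF >= `cutoff`) and subclonal
#' subsets of a mutation table carrying a `vaf` column.
#'
#' @inheritParams global_dnds
#' @param cutoff clonality boundary (VAF exactly at the boundary is
#'   clonal).
#' @return named list of `dnds_result` (`clonal`, `subclonal`); a subset
#'   without synonymous mutations yields `NULL` with a warning.
#' @export
dnds_by_clonality <- function(mutations, opp, cutoff = 0.25) {
  stopifnot("vaf" %in% names(mutations))
  run <- function(sub, scope) {
    tryCatch(global_dnds(sub, opp, scope = scope),
             error = function(e) { warning(scope, ": ", conditionMessage(e)); NULL })
  }
  list(clonal = run(mutations[mutations$vaf >= cutoff, , drop = FALSE], "clonal"),
       subclonal = run(mutations[mutations$vaf < cutoff, , drop = FALSE], "subclonal"))
}
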