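#' Per-gene mutated fraction within a cohort
#'
#' @param gm a [gene_matrix()].
#' @param cohort cohort label to summarize.
#' @return named numeric vector of mutated-patient fractions per gene.
#' @export
gene_frequencies <- function(gm, cohort) {
  sel <- gm$cohort == cohort
  if (!any(sel)) stop("empty cohort: ", cohort)
  rowMeans(gm$mat[, sel, drop = FALSE])
}

#' Merge two gene matrices on the union of genes
#'
#' Genes absent from one matrix are treated as all-wild-type in that
#' cohort, with a warning.
#'
#' @param a,b [gene_matrix()] objects with disjoint patients.
#' @return a combined [gene_matrix()].
#' @export
bind_gene_matrices <- function(a, b) {
  genes <- union(rownames(a$mat), rownames(b$mat))
  miss_a <- setdiff(genes, rownames(a$mat))
  miss_b <- setdiff(genes, rownames(b$mat))
  if (length(miss_a) || length(miss_b))
    warning("genes absent in one matrix treated as all-wild-type: ",
            paste(union(miss_a, miss_b), collapse = ", "))
  pad <- function(m, genes) {
    out <- matrix(0L, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  outc <- c(a$outcome, b$outcome)
  gene_matrix(cbind(pad(a$mat, genes), pad(b$mat, genes)),
              c(a$cohort, b$cohort),
              if (is.null(a$outcome) && is.null(b$outcome)) NULL else outc)
}

#' Per-gene mutation-frequency comparison between two cohorts
#'
#' Builds the 2x2 table (mutated/wild-type by cohort) for each gene and
#' applies the two-sided Fisher exact test, optionally with
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param gm a [gene_matrix()] containing both cohorts.
#' @param cohort_a,cohort_b cohort labels.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame per gene: mutated counts and fractions in each
#'   cohort, conditional odds ratio, `p`, and `q` (when adjusted).
#' @export
compare_frequencies <- function(gm, cohort_a, cohort_b,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sa <- gm$cohort == cohort_a
  sb <- gm$cohort == cohort_b
  if (!any(sa) || !any(sb)) stop("both cohorts must be non-empty")
  na <- sum(sa); nb <- sum(sb)
  ma <- rowSums(gm$mat[, sa, drop = FALSE])
  mb <- rowSums(gm$mat[, sb, drop = FALSE])
  res <- do.call(rbind, lapply(rownames(gm$mat), function(g) {
    ft <- stats::fisher.test(matrix(c(ma[g], na - ma[g], mb[g], nb - mb[g]),
                                    nrow = 2))
    data.frame(gene = g, n_mut_a = ma[g], n_a = na, frac_a = ma[g] / na,
               n_mut_b = mb[g], n_b = nb, frac_b = mb[g] / nb,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (adjust == "BH") res$q <- bh_adjust(res$p)
  res[order(res$p), ]
}

#' Read pathway gene sets from a two-column TSV (`pathway`, `gene`)
#'
#' @param path TSV file; the package ships the 10 canonical oncogenic
#'   signaling pathways in `inst/extdata/oncogenic_pathways.tsv`.
#' @return named list of character vectors.
#' @export
read_pathways <- function(path = system.file("extdata",
                                             "oncogenic_pathways.tsv",
                                             package = "adenomaevo")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$gene, df$pathway)
}

#' Pathway-level alteration fractions and cohort comparison
#'
#' A patient is altered in a pathway iff at least one member gene is
#' mutated. When two cohorts are named, each pathway gets a two-sided
#' Fisher comparison with BH adjustment across pathways.
#'
#' @param gm a [gene_matrix()].
#' @param sets named list of gene sets (see [read_pathways()]).
#' @param cohort_a,cohort_b cohort labels (`cohort_b` optional).
#' @return data.frame per pathway with altered fractions (and `p`, `q`
#'   when comparing).
#' @export
pathway_alteration <- function(gm, sets, cohort_a, cohort_b = NULL) {
  stopifnot(length(sets) > 0, all(lengths(sets) > 0))
  altered <- vapply(sets, function(genes) {
    present <- intersect(genes, rownames(gm$mat))
    if (!length(present)) {
      warning("pathway with no genes in matrix: fraction 0")
      return(rep(0L, ncol(gm$mat)))
    }
    as.integer(colSums(gm$mat[present, , drop = FALSE]) > 0)
  }, integer(ncol(gm$mat)))
  altered <- t(altered)  # pathways x patients
  sa <- gm$cohort == cohort_a
  if (!any(sa)) stop("empty cohort: ", cohort_a)
  out <- data.frame(pathway = names(sets),
                    frac_a = rowMeans(altered[, sa, drop = FALSE]),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort_b)) {
    sb <- gm$cohort == cohort_b
    if (!any(sb)) stop("empty cohort: ", cohort_b)
    out$frac_b <- rowMeans(altered[, sb, drop = FALSE])
    out$p <- vapply(seq_along(sets), function(i) {
      stats::fisher.test(matrix(c(sum(altered[i, sa]), sum(sa) - sum(altered[i, sa]),
                                  sum(altered[i, sb]), sum(sb) - sum(altered[i, sb])),
                                nrow = 2))$p.value
    }, numeric(1))
    out$q <- bh_adjust(out$p)
  }
  rownames(out) <- NULL
  out
}

#' Polyp-persistence risk statistic per gene
#'
#' For gene i with `mi` mutated polyp-persistent patients and `ni` mutated
#' polyp-free patients out of `M` persistent and `N` polyp-free patients
#' overall, the risk statistic is the rate ratio
#' \deqn{R_i = (m_i / n_i) / (M / N),}
#' with continuity constant 0.5 added to both numerator counts when
#' `ni = 0` (flagged). As printed this is a rate ratio, not the classical
#' odds ratio; both are reported (the classical conditional odds ratio from
#' the same 2x2 Fisher test accompanies each gene, for transparency).
#' Genes with `mi + ni < min_total` are skipped. Risk genes default to
#' `Ri > 1` with unadjusted Fisher `p <= p_flag`.
#'
#' @param inputs data.frame with columns `gene`, `mi`, `ni`.
#' @param M,N total persistent / polyp-free patient counts (> 0).
#' @param min_total minimum mutated patients for a gene to be evaluated.
#' @param p_flag Fisher-p threshold for the risk flag (default 0.1).
#' @return data.frame ranked by `Ri`: `Ri`, `odds_ratio`, `p`,
#'   `continuity_corrected`, `risk_gene`.
#' @export
persistence_risk <- function(inputs, M, N, min_total = 2L, p_flag = 0.1) {
  if (M <= 0 || N <= 0) stop("M and N must be positive")
  stopifnot(all(c("gene", "mi", "ni") %in% names(inputs)),
            all(inputs$mi >= 0), all(inputs$mi <= M),
            all(inputs$ni >= 0), all(inputs$ni <= N))
  keep <- inputs$mi + inputs$ni >= min_total
  inputs <- inputs[keep, , drop = FALSE]
  cc <- inputs$ni == 0
  c0 <- ifelse(cc, 0.5, 0)
  ri <- ((inputs$mi + c0) / (inputs$ni + c0)) / (M / N)
  stats <- lapply(seq_len(nrow(inputs)), function(i)
    stats::fisher.test(matrix(c(inputs$mi[i], M - inputs$mi[i],
                                inputs$ni[i], N - inputs$ni[i]), nrow = 2)))
  out <- data.frame(gene = inputs$gene, mi = inputs$mi, ni = inputs$ni,
                    Ri = ri,
                    odds_ratio = vapply(stats, function(s) unname(s$estimate),
                                        numeric(1)),
                    p = vapply(stats, function(s) s$p.value, numeric(1)),
                    continuity_corrected = cc,
                    stringsAsFactors = FALSE)
  out$risk_gene <- out$Ri > 1 & out$p <= p_flag
  out[order(-out$Ri), ]
}

#' @rdname persistence_risk
#' @param gm a [gene_matrix()] whose `outcome` labels contain
#'   `"persistent"` and `"polyp-free"`; counts `mi`/`ni`/`M`/`N` are
#'   derived from it.
#' @export
persistence_risk_from_matrix <- function(gm, min_total = 2L, p_flag = 0.1) {
  if (is.null(gm$outcome)) stop("gene_matrix has no outcome labels")
  per <- gm$outcome == "persistent"
  fre <- gm$outcome == "polyp-free"
  persistence_risk(
    data.frame(gene = rownames(gm$mat),
               mi = rowSums(gm$mat[, per, drop = FALSE]),
               ni = rowSums(gm$mat[, fre, drop = FALSE]),
               stringsAsFactors = FALSE),
    M = sum(per), N = sum(fre), min_total = min_total, p_flag = p_flag)
}

#' One-sided binomial enrichment test
#'
#' P(X >= k) for X ~ Binomial(n, p0): is a subgroup feature more frequent
#' than the cohort baseline?
#'
#' @param k successes (0..n).
#' @param n trials.
#' @param p0 baseline probability in (0, 1).
#' @return one-sided p-value.
#' @export
enrichment_binomial <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("k must be in 0..n")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
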