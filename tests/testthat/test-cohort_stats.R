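mk_gm <- function(counts_a, counts_b, n_a = 85, n_b = 78) {
  genes <- names(counts_a)
  mat <- matrix(0L, length(genes), n_a + n_b,
                dimnames = list(genes, c(sprintf("A%03d", 1:n_a),
                                         sprintf("B%03d", 1:n_b))))
  for (g in genes) {
    mat[g, seq_len(counts_a[[g]])] <- 1L
    mat[g, n_a + seq_len(counts_b[[g]])] <- 1L
  }
  gene_matrix(mat, setNames(rep(c("CRA", "CRC-I"), c(n_a, n_b)),
                            colnames(mat)))
}

test_that("gene frequencies are mutated fraction per cohort", {
  gm <- mk_gm(c(APC = 57, ZERO = 0), c(APC = 40, ZERO = 0))
  fr <- gene_frequencies(gm, "CRA")
  expect_equal(unname(fr["APC"]), 57 / 85, tolerance = 1e-12)
  expect_equal(unname(fr["ZERO"]), 0)
  expect_error(gene_frequencies(gm, "nope"), "empty cohort")
  # invariant to patient order
  perm <- sample(ncol(gm$mat))
  gm2 <- gene_matrix(gm$mat[, perm], gm$cohort[perm])
  expect_equal(gene_frequencies(gm2, "CRA"), fr)
})

test_that("frequency comparison reproduces printed exact-test results", {
  gm <- mk_gm(c(TP53 = 8, CTNNB1 = 9), c(TP53 = 33, CTNNB1 = 1))
  cmp <- compare_frequencies(gm, "CRA", "CRC-I", adjust = "BH")
  tp53 <- cmp[cmp$gene == "TP53", ]
  expect_equal(tp53$p, 1.4e-6, tolerance = 0.03)
  ctnnb1 <- cmp[cmp$gene == "CTNNB1", ]
  expect_equal(ctnnb1$p, 0.019, tolerance = 0.01)
  expect_true(all(cmp$q >= cmp$p))
})

test_that("swapping cohorts preserves p and inverts the odds ratio", {
  gm <- mk_gm(c(G1 = 20, G2 = 5), c(G1 = 8, G2 = 12))
  ab <- compare_frequencies(gm, "CRA", "CRC-I")
  ba <- compare_frequencies(gm, "CRC-I", "CRA")
  m <- match(ab$gene, ba$gene)
  expect_equal(ab$p, ba$p[m], tolerance = 1e-12)
  expect_equal(ab$odds_ratio, 1 / ba$odds_ratio[m], tolerance = 1e-6)
})

test_that("identical cohorts give p = 1 everywhere", {
  gm <- mk_gm(c(G1 = 10, G2 = 30), c(G1 = 10, G2 = 30), n_a = 50, n_b = 50)
  cmp <- compare_frequencies(gm, "CRA", "CRC-I")
  expect_equal(cmp$p, rep(1, nrow(cmp)), tolerance = 1e-9)
})

test_that("type-I error of the per-gene test is controlled under the null", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    mat <- matrix(rbinom(40 * 60, 1, 0.2), 40, 60,
                  dimnames = list(paste0("g", 1:40), paste0("p", 1:60)))
    gm <- gene_matrix(mat, setNames(rep(c("CRA", "CRC-I"), each = 30),
                                    colnames(mat)))
    mean(compare_frequencies(gm, "CRA", "CRC-I")$p <= 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.075)
})

test_that("a singleton pathway reduces to its gene frequency", {
  gm <- mk_gm(c(APC = 57, KRAS = 33), c(APC = 44, KRAS = 22))
  pa <- pathway_alteration(gm, list(ONLY_APC = "APC"), "CRA")
  expect_equal(pa$frac_a, unname(gene_frequencies(gm, "CRA")["APC"]))
  # pathway with no genes present warns and yields 0
  expect_warning(pa0 <- pathway_alteration(gm, list(EMPTYP = "ZZZ"), "CRA"),
                 "no genes")
  expect_equal(pa0$frac_a, 0)
})

test_that("disjoint pathways covering all genes count every mutated patient", {
  gm <- mk_gm(c(G1 = 30, G2 = 20), c(G1 = 10, G2 = 40))
  pa <- pathway_alteration(gm, list(P1 = "G1", P2 = "G2"), "CRA")
  mutated_any <- mean(colSums(gm$mat[, gm$cohort == "CRA"]) > 0)
  covered <- colSums(gm$mat[, gm$cohort == "CRA", drop = FALSE]) > 0
  expect_lte(mutated_any, sum(pa$frac_a))
})

test_that("planted pathway enrichment is recovered at BH 0.1", {
  sets <- list(HOT = paste0("h", 1:5), COLD = paste0("c", 1:5))
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    genes <- c(paste0("h", 1:5), paste0("c", 1:5))
    fa <- c(rep(0.15, 5), rep(0.05, 5))  # 3x enrichment in cohort A
    fb <- rep(0.05, 10)
    mat <- t(vapply(seq_along(genes), function(i)
      c(rbinom(85, 1, fa[i]), rbinom(78, 1, fb[i])), integer(163)))
    rownames(mat) <- genes
    colnames(mat) <- paste0("p", 1:163)
    gm <- gene_matrix(mat, setNames(rep(c("A", "B"), c(85, 78)),
                                    colnames(mat)))
    pa <- pathway_alteration(gm, sets, "A", "B")
    pa$q[pa$pathway == "HOT"] <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("persistence risk implements the printed rate-ratio formula", {
  # null forcing: mi/ni = M/N exactly -> Ri = 1
  r0 <- persistence_risk(data.frame(gene = "G", mi = 23, ni = 19), 23, 19,
                         min_total = 2)
  expect_equal(r0$Ri, 1, tolerance = 1e-12)
  # worked example: mi 6, ni 1 with M 23, N 19
  r1 <- persistence_risk(data.frame(gene = "KMT2C", mi = 6, ni = 1), 23, 19)
  expect_equal(r1$Ri, (6 / 1) / (23 / 19), tolerance = 1e-12)
  expect_equal(r1$Ri, 4.957, tolerance = 1e-3)
  # degenerate ni = 0 handled by continuity constant
  r2 <- persistence_risk(data.frame(gene = "G", mi = 4, ni = 0), 23, 19)
  expect_true(is.finite(r2$Ri))
  expect_true(r2$continuity_corrected)
  expect_equal(r2$Ri, (4.5 / 0.5) / (23 / 19), tolerance = 1e-12)
  # scale invariance
  r3 <- persistence_risk(data.frame(gene = "G", mi = 12, ni = 2), 46, 38)
  expect_equal(r3$Ri, r1$Ri, tolerance = 1e-12)
  expect_error(persistence_risk(data.frame(gene = "G", mi = 1, ni = 1), 0, 19),
               "positive")
  # genes below min_total are skipped
  r4 <- persistence_risk(data.frame(gene = c("A", "B"), mi = c(1, 5),
                                    ni = c(0, 2)), 23, 19, min_total = 2)
  expect_equal(r4$gene, "B")
})

test_that("matrix-derived persistence counts match the direct interface", {
  set.seed(8)
  mat <- matrix(rbinom(10 * 42, 1, 0.3), 10, 42,
                dimnames = list(paste0("g", 1:10), paste0("p", 1:42)))
  outcome <- setNames(rep(c("persistent", "polyp-free"), c(23, 19)),
                      colnames(mat))
  gm <- gene_matrix(mat, setNames(rep("CRA", 42), colnames(mat)), outcome)
  a <- persistence_risk_from_matrix(gm)
  b <- persistence_risk(data.frame(gene = rownames(mat),
                                   mi = rowSums(mat[, 1:23]),
                                   ni = rowSums(mat[, 24:42])), 23, 19)
  expect_equal(a, b)
})

test_that("binomial enrichment matches the upper-tail definition", {
  expect_equal(enrichment_binomial(3, 5, 19 / 85), 0.0776, tolerance = 1e-3)
  expect_equal(enrichment_binomial(0, 5, 0.3), 1)
  expect_equal(enrichment_binomial(5, 5, 0.999), 0.999^5, tolerance = 1e-12)
  expect_error(enrichment_binomial(3, 5, 0), "p0")
  expect_error(enrichment_binomial(6, 5, 0.2), "0..n")
})
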