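test_that("clonality split is exhaustive, disjoint, boundary-clonal", {
  s <- split_clonality(c(0.4, 0.25, 0.24))
  expect_setequal(s$clonal, c(0.4, 0.25))
  expect_equal(s$subclonal, 0.24)
  e <- split_clonality(numeric(0))
  expect_equal(lengths(e), c(clonal = 0L, subclonal = 0L))
  set.seed(5)
  v <- runif(500, 0.01, 0.99)
  s2 <- split_clonality(v)
  expect_setequal(c(s2$clonal, s2$subclonal), v)
  expect_equal(s2$subclonal, v[v < 0.25])
})

test_that("exact-model spectra give R^2 = 1 to machine precision", {
  f <- simulate_neutral_vafs(sim_config(seed = 2), n = 300, noiseless = TRUE)
  fit <- neutrality_test(f)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$is_neutral)
})

test_that("R^2 is invariant to duplicating the whole spectrum", {
  f <- simulate_neutral_vafs(sim_config(seed = 4), n = 400)
  expect_equal(neutrality_test(c(f, f))$r_squared,
               neutrality_test(f)$r_squared, tolerance = 1e-12)
})

test_that("a dominant subclonal cluster breaks the 1/f fit", {
  bad <- vapply(1:20, function(s)
    neutrality_test(simulate_selected_vafs(sim_config(seed = s)))$r_squared,
    numeric(1))
  expect_gte(mean(bad < 0.98), 0.9)
})

test_that("too few subclonal mutations yield a not-evaluable result", {
  fit <- neutrality_test(runif(8, 0.11, 0.24))
  expect_false(fit$evaluable)
  expect_true(is.na(fit$is_neutral))
})

test_that("opportunity table matches hand-enumerated codon arithmetic", {
  # ATG: every one of the 9 substitutions changes the amino acid
  o <- build_opportunity_table(c(g1 = "ATG"))
  expect_equal(sum(o$N), 9)
  expect_equal(sum(o$S), 0)
  # glycine runs: all 3rd-position changes are synonymous
  o2 <- build_opportunity_table(c(g2 = strrep("GGG", 10)))
  expect_equal(sum(o2$S), 30)
  expect_equal(sum(o2$N), 60)
  # conservation: totals are 3 x coding length
  opp <- cached_opportunity()
  expect_equal(unname(rowSums(opp$N + opp$S)), unname(3 * opp$lengths))
  # internal stop is rejected with the gene named
  expect_error(build_opportunity_table(c(bad = "ATGTAAATG")), "bad")
})

test_that("dN/dS arithmetic: linearity, synonymous-only, rate anchoring", {
  opp <- toy_opportunity()
  m <- toy_mutations(n_syn_gA = 10, n_nonsyn_gB = 5, n_nonsyn_gA = 5)
  d1 <- global_dnds(m, opp)
  # rate = 10/100, opportunities 60 -> expected 6
  expect_equal(d1$expected_n, 6)
  expect_equal(d1$dnds, 10 / 6, tolerance = 1e-12)
  # doubling every nonsynonymous count doubles dN/dS
  m2 <- rbind(m, m[m$class == "nonsynonymous", ])
  expect_equal(global_dnds(m2, opp)$dnds, 2 * d1$dnds, tolerance = 1e-12)
  # synonymous-only input -> dN/dS = 0
  expect_equal(global_dnds(toy_mutations(10, 0, 0), opp)$dnds, 0)
  # no synonymous mutations -> unidentifiable
  expect_error(global_dnds(toy_mutations(0, 5, 0), opp), "unidentifiable")
})

test_that("per-gene dN/dS flags only significant excess", {
  opp <- toy_opportunity()
  # gA: expected = rate 0.1 * 50 = 5; observed 5 -> dnds 1, not flagged
  g <- gene_dnds(toy_mutations(10, 10, 5), opp)
  ga <- g[g$gene == "gA", ]; gb <- g[g$gene == "gB", ]
  expect_equal(ga$dnds, 1, tolerance = 1e-12)
  expect_false(ga$selected)
  # gB: expected 1.0, observed 10 -> Poisson tail by direct summation
  expect_equal(gb$expected_n, 1, tolerance = 1e-12)
  expect_equal(gb$p_value, sum(dpois(10:200, 1)), tolerance = 1e-9)
  expect_true(gb$selected)
})

test_that("global dN/dS recovers planted selection coefficients in its CI", {
  opp <- cached_opportunity()
  for (w in c(0.5, 1, 2, 5)) {
    m <- simulate_coding_mutations(opp, n = 2000, w = w, seed = 20 + w)
    d <- global_dnds(m, opp)
    expect_gte(w, d$ci_low)
    expect_lte(w, d$ci_high)
  }
})

test_that("clonality-split dN/dS partitions the mutation set", {
  opp <- cached_opportunity()
  m <- simulate_coding_mutations(opp, n = 1000, w = 1, seed = 3,
                                 vafs = runif(1000, 0.05, 0.6))
  both <- dnds_by_clonality(m, opp)
  expect_equal(both$clonal$scope, "clonal")
  expect_equal(both$clonal$n_syn + both$subclonal$n_syn,
               sum(m$class == "synonymous"))
})

test_that("shared mutation keys decide a common ancestral origin", {
  p2 <- list(lesion1 = c("chr5:112:C>T", "chr12:25:G>A", "chr1:99:A>G"),
             lesion2 = c("chr5:112:C>T", "chr12:25:G>A", "chr7:14:T>C"))
  r <- shared_mutation_origin(p2)
  expect_equal(r$origin, "shared-ancestor")
  expect_setequal(r$shared_keys, c("chr5:112:C>T", "chr12:25:G>A"))
  r2 <- shared_mutation_origin(list(a = c("k1", "k2"), b = c("k3")))
  expect_equal(r2$origin, "independent")
  r3 <- shared_mutation_origin(list(a = c("k1"), b = c("k1"), c = c("k9")))
  expect_equal(r3$origin, "shared-ancestor")
  expect_equal(nrow(r3$pairs), 1)
  expect_error(shared_mutation_origin(list(a = "k1")), "two lesions")
})
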