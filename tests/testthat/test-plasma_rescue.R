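test_that("fisher_site_test matches direct combinatorial enumeration", {
  expect_equal(fisher_site_test(5, 995, 0, 2000),
               oracle_fisher(5, 995, 0, 2000), tolerance = 1e-12)
  # exhaustive over a lattice of small tables
  for (cf_alt in 0:6) for (ctrl_alt in 0:4)
    expect_equal(fisher_site_test(cf_alt, 12 - cf_alt, ctrl_alt, 20 - ctrl_alt),
                 oracle_fisher(cf_alt, 12 - cf_alt, ctrl_alt, 20 - ctrl_alt),
                 tolerance = 1e-12)
})

test_that("non-enriched and degenerate tables are non-significant", {
  # identical proportions: no enrichment, p stays in the upper tail
  p_same <- fisher_site_test(3, 997, 6, 1994)
  expect_equal(p_same, oracle_fisher(3, 997, 6, 1994), tolerance = 1e-12)
  expect_gt(p_same, 0.5)
  expect_equal(fisher_site_test(0, 1000, 0, 2000), 1)
  expect_warning(p0 <- fisher_site_test(0, 0, 0, 0), "all-zero")
  expect_equal(p0, 1)
})

test_that("BH adjustment follows the step-up rule and is order invariant", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.003, 0.2, 0.04, 0.9, 0.012)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("rescue applies the three detection criteria and names failures", {
  tv <- data.frame(patient_id = "P1", key = paste0("k", 1:4))
  counts <- data.frame(
    patient_id = "P1", key = paste0("k", 1:4),
    cf_alt = c(3L, 22L, 30L, 0L), cf_ref = c(10L, 1478L, 1970L, 1500L),
    ctrl_alt = c(0L, 18L, 0L, 0L), ctrl_ref = c(2000L, 1982L, 2000L, 2000L))
  res <- rescue(tv, counts)
  # k1: tiny p (3 alt in a shallow cfDNA pileup vs deep clean control)
  # but 3 < 4 alt reads
  expect_lt(res$q_value[1], 0.1)
  expect_false(res$detected[1])
  expect_equal(res$failed_rules[1], "min_alt_reads")
  # k2: cf_vaf 22/1500 = 0.0147 < 2 * 18/2000 = 0.018 regardless of p
  expect_false(res$detected[2])
  expect_match(res$failed_rules[2], "vaf_ratio")
  # k3: all three criteria pass
  expect_true(res$detected[3])
  expect_equal(res$failed_rules[3], "")
  # k4: nothing there
  expect_false(res$detected[4])
})

test_that("with clean control and >= 4 alt reads detection reduces to the q rule", {
  tv <- data.frame(patient_id = "P1", key = paste0("k", 1:6))
  counts <- data.frame(patient_id = "P1", key = paste0("k", 1:6),
                       cf_alt = c(4L, 5L, 8L, 12L, 20L, 4L),
                       cf_ref = 1500L - c(4L, 5L, 8L, 12L, 20L, 4L),
                       ctrl_alt = 0L, ctrl_ref = 2000L)
  res <- rescue(tv, counts)
  expect_equal(res$detected, res$q_value <= 0.1)
})

test_that("detection is monotone in cfDNA alt reads", {
  p <- vapply(2:40, function(a) fisher_site_test(a, 1500 - a, 0, 2000),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("sites without counts are reported untested, not undetected", {
  tv <- data.frame(patient_id = "P1", key = c("k1", "k2"))
  counts <- data.frame(patient_id = "P1", key = "k1", cf_alt = 30L,
                       cf_ref = 1470L, ctrl_alt = 0L, ctrl_ref = 2000L)
  res <- rescue(tv, counts)
  expect_true(res$detected[1])
  expect_true(is.na(res$detected[2]))
  expect_equal(res$failed_rules[2], "untested")
})

test_that("shed variants at VAF >= 1% are recovered with >= 95% sensitivity", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s)
    ps <- simulate_plasma_counts(cfg, n_shed = 10, n_unshed = 10,
                                 shed_vafs = runif(10, 0.01, 0.03))
    tv <- data.frame(patient_id = "P1", key = ps$truth$key)
    res <- rescue(tv, ps$counts)
    sum(res$detected & ps$truth$shed) / sum(ps$truth$shed)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("nothing is detected when no variant sheds", {
  fp <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 1000 + s)
    ps <- simulate_plasma_counts(cfg, n_shed = 0, n_unshed = 20)
    res <- rescue(data.frame(patient_id = "P1", key = ps$truth$key),
                  ps$counts)
    mean(res$detected)
  }, numeric(1))
  expect_lte(mean(fp), 0.01)
})

test_that("cohort summary handles the all and none edge cases", {
  none <- cohort_detection_summary(
    data.frame(patient_id = character(0), gene = character(0)), 10)
  expect_equal(none$detection_rate, 0)
  all3 <- cohort_detection_summary(
    data.frame(patient_id = c("A", "B", "C"), gene = "KRAS"), 3)
  expect_equal(all3$detection_rate, 1)
  expect_error(cohort_detection_summary(data.frame(), 0), "positive")
})
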