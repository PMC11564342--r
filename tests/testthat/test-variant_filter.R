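mk_call <- function(patient = "P1", type = "tissue", pos = 1000,
                    ref = "A", alt = "T", caller = "varscan2", vaf = 0.2,
                    depth = 1000L, pop1 = NA, pope = NA, mapq = 0.9,
                    normal_vaf = NULL) {
  df <- data.frame(patient_id = patient, sample_type = type, chrom = "chr1",
                   pos = pos, ref = ref, alt = alt, caller = caller,
                   vaf = vaf, depth = depth, alt_reads = round(vaf * depth),
                   pop_af_1kg = pop1, pop_af_exac = pope,
                   mappability = mapq, gene = NA, variant_class = "missense",
                   protein_change = NA, stringsAsFactors = FALSE)
  if (!is.null(normal_vaf)) df$normal_vaf <- normal_vaf
  df
}

test_that("tissue consensus keeps two-caller variants and drops singletons", {
  calls <- normalize_calls(somatic_calls(rbind(
    mk_call(pos = 1000, caller = "varscan2"),
    mk_call(pos = 1000, caller = "strelka"),
    mk_call(pos = 2000, caller = "strelka"))))
  out <- consensus_merge(calls, "tissue")
  expect_equal(out$variants$key, "chr1:1000:A>T")
  expect_equal(out$report$removed$rules, "consensus_min_callers")
  expect_equal(out$report$n_kept + out$report$n_removed, out$report$n_input)
})

test_that("plasma rules enforce normal VAF zero and the single-caller VAF floor", {
  calls <- normalize_calls(somatic_calls(rbind(
    mk_call(type = "plasma", pos = 1000, vaf = 0.06, normal_vaf = 0),
    mk_call(type = "plasma", pos = 2000, vaf = 0.04, normal_vaf = 0),
    mk_call(type = "plasma", pos = 3000, vaf = 0.30, normal_vaf = 0.02))))
  out <- consensus_merge(calls, "plasma")
  expect_equal(out$variants$key, "chr1:1000:A>T")
  rules <- setNames(out$report$removed$rules, out$report$removed$key)
  expect_match(rules[["chr1:2000:A>T"]], "plasma_single_caller_vaf")
  expect_match(rules[["chr1:3000:A>T"]], "plasma_normal_vaf")
  # missing normal VAF is an error in plasma mode
  nn <- normalize_calls(somatic_calls(mk_call(type = "plasma")))
  expect_error(consensus_merge(nn, "plasma"), "matched-normal VAF")
})

test_that("consensus agrees with a brute-force grouping oracle on 200 calls", {
  set.seed(31)
  n <- 200
  calls <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_call(patient = sample(c("P1", "P2"), 1),
            pos = sample(seq(1000, 200000, by = 1000), 1),
            caller = sample(c("varscan2", "strelka", "gvc"), 1),
            vaf = runif(1, 0.05, 0.5))))
  calls <- normalize_calls(somatic_calls(calls))
  out <- consensus_merge(calls, "tissue")
  # oracle: group keys independently, keep those with >= 2 distinct callers
  grp <- paste(calls$patient_id, calls$key)
  ncall <- tapply(calls$caller, grp, function(x) length(unique(x)))
  oracle_kept <- names(ncall)[ncall >= 2]
  expect_setequal(paste(out$variants$patient_id, out$variants$key),
                  oracle_kept)
  # merged VAF comes from the deepest caller (all same depth here: any row)
  expect_true(all(out$variants$n_callers >= 2))
})

test_that("population AF and mappability rules remove annotated artifacts", {
  vars <- consensus_merge(normalize_calls(somatic_calls(rbind(
    mk_call(pos = 1000, caller = "varscan2", pop1 = 0.02),
    mk_call(pos = 1000, caller = "strelka", pop1 = 0.02),
    mk_call(pos = 5000, caller = "varscan2", mapq = 0.5),
    mk_call(pos = 5000, caller = "strelka", mapq = 0.5),
    mk_call(pos = 9000, caller = "varscan2"),
    mk_call(pos = 9000, caller = "strelka")))), "tissue")$variants
  out <- quality_filters(vars)
  expect_equal(out$variants$key, "chr1:9000:A>T")
  rules <- setNames(out$report$removed$rules, out$report$removed$key)
  expect_equal(unname(rules["chr1:1000:A>T"]), "population_af")
  expect_equal(unname(rules["chr1:5000:A>T"]), "mappability")
})

test_that("the 100 bp proximity boundary is inclusive on the kept side", {
  two_at <- function(p1, p2) consensus_merge(normalize_calls(somatic_calls(rbind(
    mk_call(pos = p1, caller = "varscan2"), mk_call(pos = p1, caller = "strelka"),
    mk_call(pos = p2, ref = "G", alt = "C", caller = "varscan2"),
    mk_call(pos = p2, ref = "G", alt = "C", caller = "strelka")))),
    "tissue")$variants
  close_pair <- quality_filters(two_at(1000, 1099))
  expect_equal(nrow(close_pair$variants), 0)
  expect_true(all(grepl("proximity", close_pair$report$removed$rules)))
  far_pair <- quality_filters(two_at(1000, 1100))
  expect_equal(nrow(far_pair$variants), 2)
})

test_that("proximity removal matches the O(n^2) pairwise-distance oracle", {
  set.seed(77)
  pos <- sample(seq(1000, 40000, by = 17), 60)
  vars <- consensus_merge(normalize_calls(somatic_calls(do.call(rbind, c(
    lapply(pos, function(p) mk_call(pos = p, caller = "varscan2")),
    lapply(pos, function(p) mk_call(pos = p, caller = "strelka")))))),
    "tissue")$variants
  out <- quality_filters(vars)
  dmat <- abs(outer(vars$pos, vars$pos, "-"))
  diag(dmat) <- Inf
  oracle_removed <- vars$key[apply(dmat < 100, 1, any)]
  expect_setequal(setdiff(vars$key, out$variants$key), oracle_removed)
})

test_that("annotation filters commute with consensus merging", {
  sim <- simulate_multicaller_calls(sim_config(seed = 9))
  calls <- sim$calls
  # route A: consensus then quality (the pipeline order)
  a <- apply_filters(calls, "tissue")$variants$key
  # route B: annotation rules on raw calls, then consensus, then proximity
  af1 <- ifelse(is.na(calls$pop_af_1kg), 0, calls$pop_af_1kg)
  af2 <- ifelse(is.na(calls$pop_af_exac), 0, calls$pop_af_exac)
  pre <- calls[pmax(af1, af2) <= 0.01 &
                 (is.na(calls$mappability) | calls$mappability >= 0.75), ]
  cons <- consensus_merge(pre, "tissue")$variants
  cfg_noann <- filter_config(max_pop_af = 1, min_mappability = 0)
  b <- quality_filters(cons, cfg_noann)$variants$key
  expect_setequal(a, b)
})

test_that("relaxing any threshold never shrinks the kept set", {
  sim <- simulate_multicaller_calls(sim_config(seed = 13))
  strict <- apply_filters(sim$calls, "tissue", filter_config())$variants$key
  for (cfg in list(filter_config(max_pop_af = 0.10),
                   filter_config(min_mappability = 0.4),
                   filter_config(min_pair_distance = 10L),
                   filter_config(min_callers_tissue = 1L))) {
    relaxed <- apply_filters(sim$calls, "tissue", cfg)$variants$key
    expect_true(all(strict %in% relaxed))
  }
})
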