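# Shared fixtures and independent oracles, built in code at test time.

# Reference chromosome with a known A-homopolymer at positions 101-104,
# flanked by C (100) and T (105), for indel-normalization tests.
make_reference <- function() {
  set.seed(42)
  chr <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  substr(chr, 100, 105) <- "CAAAAT"
  c(chr1 = chr)
}

# A 50-call synthetic table for round-trip tests.
make_calls <- function(n = 50, seed = 7) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  depth <- sample(500:1500, n, replace = TRUE)
  alt_reads <- rbinom(n, depth, 0.3)
  somatic_calls(data.frame(
    patient_id = sample(c("P1", "P2"), n, replace = TRUE),
    sample_type = "tissue",
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample(1e5, n), ref = ref, alt = unname(alt),
    caller = sample(c("varscan2", "strelka", "gvc"), n, replace = TRUE),
    vaf = alt_reads / depth, depth = depth, alt_reads = alt_reads,
    pop_af_1kg = NA, pop_af_exac = NA, mappability = 0.9,
    gene = "GENE1", variant_class = "missense", protein_change = NA,
    stringsAsFactors = FALSE))
}

# All-pairs concordance AUC (ties count 0.5): the O(n^2) oracle.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# One-sided (cfDNA-enriched) Fisher p by direct combinatorial enumeration
# over the hypergeometric support, independent of phyper.
oracle_fisher <- function(cf_alt, cf_ref, ctrl_alt, ctrl_ref) {
  n1 <- cf_alt + cf_ref; n2 <- ctrl_alt + ctrl_ref
  k <- cf_alt + ctrl_alt
  if (n1 + n2 == 0) return(1)
  js <- max(0, k - n2):min(n1, k)
  pr <- exp(lchoose(n1, js) + lchoose(n2, k - js) - lchoose(n1 + n2, k))
  sum(pr[js >= cf_alt])
}

# Lazily built, cached CDS/opportunity fixture shared across dN/dS tests.
.opp_cache <- new.env(parent = emptyenv())
cached_opportunity <- function(n_genes = 60, n_codons = 200, seed = 11) {
  key <- paste(n_genes, n_codons, seed, sep = "_")
  if (is.null(.opp_cache[[key]])) {
    cds <- simulate_cds(n_genes, n_codons, seed = seed)
    .opp_cache[[key]] <- build_opportunity_table(cds)
  }
  .opp_cache[[key]]
}

# Hand-built opportunity table for exact-arithmetic dN/dS tests: one
# context with known synonymous/nonsynonymous opportunities.
toy_opportunity <- function() {
  ctx <- "ACA>T"
  N <- matrix(c(50, 10), nrow = 2, dimnames = list(c("gA", "gB"), ctx))
  S <- matrix(c(100, 0), nrow = 2, dimnames = list(c("gA", "gB"), ctx))
  structure(list(N = N, S = S, lengths = c(gA = 50, gB = 10)),
            class = "opportunity_table")
}

toy_mutations <- function(n_syn_gA = 10, n_nonsyn_gB = 10, n_nonsyn_gA = 0) {
  data.frame(
    gene = c(rep("gA", n_syn_gA + n_nonsyn_gA), rep("gB", n_nonsyn_gB)),
    context = "ACA>T",
    class = c(rep("synonymous", n_syn_gA),
              rep("nonsynonymous", n_nonsyn_gA + n_nonsyn_gB)),
    stringsAsFactors = FALSE)
}
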