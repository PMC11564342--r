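---
title: "Methods: somatic analysis of adenoma tissue and plasma panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic analysis of adenoma tissue and plasma panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenomaevo)
```

## Scope and model of the data

`adenomaevo` analyses targeted panel sequencing of colorectal adenoma (CRA)
tissue with matched plasma cell-free DNA (cfDNA) and leukocyte controls.
The working model of the data is: a 451-gene panel spanning 3.34 Mb,
sequenced to mean depths of roughly 1000x in tissue, 1500x in plasma and
2000x in the control; somatic candidates produced by three independent
callers, each with imperfect sensitivity and caller-specific artifacts;
and a premalignant lesion whose tumor fraction in plasma is tiny (shed
VAFs around 1–3%), so plasma presence of a tissue mutation must be decided
by counting reads rather than by de novo calling.

The package is organised as the pipeline a practitioner would run:
consensus filtering of calls, tumor-informed plasma rescue, burden
metrics, clonal-evolution statistics, cohort comparisons, and a
CRA-vs-CRC classifier — with a synthetic-data module that generates every
input with known truth so each stage is testable end to end.

## Consensus and quality filtering

Tissue variants are kept when at least two distinct callers report the
same normalized allele. Plasma variants additionally require a
matched-normal VAF of zero, and single-caller plasma variants a VAF of at
least 0.05. Quality rules remove variants with population allele
frequency above 0.01 in either 1000 Genomes or ExAC, with site
mappability below 0.75, and any set of same-sample variants closer than
100 bp.

Three behaviours deserve explicit statement:

* **Missing population AF is treated as 0.** Absence from a population
  database is evidence of rarity, not a missing measurement; each such
  record is counted in the filter report.
* **Proximity clusters are removed whole.** The 100 bp rule names no
  survivor; we treat sub-100 bp clusters as alignment artifacts and drop
  every member. The boundary is inclusive on the kept side: variants
  exactly 100 bp apart survive.
* **Rule order.** The proximity rule is evaluated on the post-consensus
  variant set of each patient+sample (single-caller noise should not
  poison a real variant's neighborhood). The two annotation rules commute
  with consensus merging, and the test suite checks that invariance; the
  pipeline's canonical order is consensus first, then quality rules.

## Tumor-informed plasma rescue

For each tissue mutation, alt/ref read counts at the site in cfDNA and
control form a 2x2 table. The test is the one-sided Fisher exact test
(hypergeometric tail) for cfDNA enrichment — one-sided because rescue asks
only whether the mutation is present in plasma. Per patient, p-values are
Benjamini–Hochberg adjusted across that patient's tissue-variant sites; a
site is detected iff q <= 0.1, cfDNA VAF >= 2x the control VAF, and at
least 4 alt reads support it. VAFs in these criteria are computed from
the pileup counts, never from a caller's VAF field. Sites with no counts
are reported untested rather than undetected.

At the study's depths these thresholds give near-complete sensitivity for
shed VAFs of 1% and above (the suite measures >= 95% over 100 simulation
seeds) while a clean control and the 4-read floor keep the false
detection rate at background-error level.

## Burden metrics

TMB is qualifying mutations per megabase of panel (default 3.34 Mb). The
numerator defaults to nonsynonymous mutations (missense, nonsense,
frameshift, splice) and can be switched to all mutations; the definition
is explicit because published medians are not reproducible without fixing
it. GII is the fraction of the segmented genome in copy-number gain, loss
or copy-neutral LOH, classified per segment against a baseline ploidy of
2 (a sample's rounded ploidy can be substituted). The denominator is the
segmented length, not a fixed genome size, so targeted data behave
sensibly; whether a published GII used the whole genome or the covered
genome is generally unstated, and this choice is the conservative one for
panel data.

## Neutral-evolution statistic

Under neutral growth the cumulative count of subclonal mutations with
frequency at least f is linear in 1/f:
M(f) = (mu/beta)(1/f − 1/f_max). The fit takes mutations with VAF
strictly inside (0.1, 0.25), evaluates M at each observed VAF (ties
collapsed), and regresses M on x = 1/f − 1/f_max through the origin by
ordinary least squares. R² is computed against the mean of M (it can be
negative and is clipped at 0); samples with R² >= 0.98 are classified
neutrally evolved. A fit needs at least 12 subclonal mutations —
below that the result is flagged not evaluable rather than classified.
Raw VAFs are used without purity or copy-number correction because the
window boundaries are themselves stated on raw VAF.

The synthetic generator draws frequencies from the density proportional
to 1/f² (so M(f) is exactly linear in expectation) and applies binomial
read noise; its noiseless mode places frequencies on exact model
quantiles, for which R² = 1 to machine precision — a useful smoke test
that the fit's algebra is right.

## dN/dS selection estimation

Opportunity counts are tabulated per gene over the 96 strand-collapsed
trinucleotide contexts: for every coding position and every possible
substitution, the change is synonymous or nonsynonymous under the
standard genetic code. Totals per gene are exactly 3x the coding length;
the first and last base of a CDS take an `A` padding flank for their
context. Context-specific mutation rates are estimated from synonymous
counts over synonymous opportunities, pooled across genes; the expected
nonsynonymous count is the rate-weighted opportunity sum and dN/dS is
observed over expected. The 95% CI is a delta-method interval on the log
ratio that combines the Poisson variance of the observed count with the
sampling variance of the estimated expectation — a Poisson-only interval
undercovers noticeably whenever synonymous counts are modest (measured
~70% coverage at 2000 mutations, versus 84–96% for the combined
interval).

One numerical subtlety matters: a few contexts have zero synonymous
opportunity (their rate is unidentifiable) yet carry ~5% of
nonsynonymous opportunity. Counting their observed mutations while
contributing nothing to the expectation biases dN/dS upward by ~30% on
neutral data; the estimator therefore restricts both the observed and
expected counts to rate-identifiable contexts. With that restriction,
neutral simulations (2000 mutations, 100-gene CDS set) give a mean dN/dS
of 1.00, and planted selection coefficients w in {0.5, 1, 2, 5} are
recovered within the CI.

Per-gene dN/dS uses cohort-wide rates and a one-sided Poisson test of the
gene's observed nonsynonymous count against its expectation; genes with
dN/dS > 1 and p <= 0.05 are flagged positively selected. P-values are
reported unadjusted (whether published gene-level analyses adjusted is
typically unstated); the alpha is a parameter.

## Cohort statistics

Per-gene cohort comparisons are two-sided Fisher exact tests on
mutated/wild-type 2x2 tables, optionally BH-adjusted. Pathway-level
comparisons mark a patient altered when any member gene is mutated; the
ten canonical oncogenic signaling pathway memberships ship as an editable
TSV (`inst/extdata/oncogenic_pathways.tsv`) — they are data, not code.

The polyp-persistence statistic for gene i is the rate ratio
R_i = (m_i/n_i)/(M/N) over persistent (M) and polyp-free (N) follow-up
groups. As printed this is not the classical odds ratio; the package
implements the printed formula and reports the conditional odds ratio
from the same table alongside, for transparency. When n_i = 0 a
continuity constant of 0.5 is added to both numerator counts and the gene
is flagged. Risk genes default to R_i > 1 with unadjusted Fisher
p <= 0.1; both thresholds are parameters, since the published six-gene
persistence list states no explicit cutoff.

## Random-forest classifier and minimal depth

The CRA-vs-CRC classifier is a 1000-tree random forest on the binary
gene-by-patient matrix. Discovery-set scores are out-of-bag vote
fractions (preventing optimism); validation sets use plain vote
fractions. AUC is computed by the rank statistic (ties as 1/2), which the
tests pin against an all-pairs concordance oracle; AUCPR by step
integration of the precision-recall curve.

Variable selection uses minimal depth: the depth of a variable's first
split in a tree, penalised with max depth + 1 when the tree never uses
it. Three threshold rules are exposed:

* `permutation` (default): the forest is refit on label-permuted data and
  the threshold is the 5% quantile of the pooled per-gene mean *relative*
  minimal depths (each tree's depths scaled by its penalty depth, making
  forests with different tree sizes comparable). This null preserves the
  matrix's carrier-count structure, so chance gene–label association —
  which on n≈160 panels is substantial — is part of the null.
* `mean` and `quantile`: the analytic null in which every split node of
  the observed trees picks a given variable with probability 1/p. These
  are the textbook constructions; on binary mutation matrices they run
  anti-conservative precisely because they ignore per-dataset carrier
  luck (we measured 10–35% noise-gene contamination on planted-signal
  fixtures, versus ~0.2% for the permutation rule at matched recovery).

On the planted fixture (15 informative genes at 3–5x frequency ratios,
200 background genes at 5%, cohort sizes 85/78) the default rule recovers
on average more than 12 of 15 informative genes with well under 5%
contamination across 50 seeds, at 1000 trees and 3 permuted refits.

## The synthetic cohort: what it does and does not emulate

The generators emulate: caller-discordant call sets with planted
artifact classes (common-SNP contaminants, low-mappability sites,
sub-100 bp clusters, single-caller noise); plasma shedding at VAF 0.92–3%
against 1500x/2000x depths with clean controls; segment plans hitting an
exact target GII; 1/f subclonal spectra with binomial depth noise;
context-dependent coding mutations with per-gene selection coefficients;
and cohort matrices at configured per-gene frequencies (defaults follow
the frequently-reported adenoma/carcinoma values: APC 0.67/0.56, KRAS
0.39/0.28, TP53 0.09/0.42, PIK3CA 0.04/0.14, CTNNB1 0.11/0.01, ...;
genes without published point values take one-time realistic settings).
One master seed fans out to independent per-generator streams, so adding
a generator never perturbs another's draws.

They do not emulate: read-level errors (FFPE damage, UMI structure),
linkage between genes (draws are independent Bernoulli), subclonal
population structure beyond a single planted cluster, or purity/ploidy
distortion of VAFs. Passing tests therefore demonstrate correctness of
the statistics under their stated models, not robustness to every
artifact of real panels.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 100 seeds for the
neutrality and dN/dS calibrations (n = 1000–2000 mutations each), a
100-gene x 300-codon CDS set for opportunity tables, 50 seeds x 1000
trees for the selection-recovery study, and exhaustive enumeration of all
2x2 tables with margins up to 50 for the Fisher oracle. These sizes give
stable Monte-Carlo estimates (SE well inside the asserted tolerances) at
desk-scale runtimes. Ties in VAF spectra are collapsed before the 1/f
fit; p-values are clipped into (0, 1]; all-zero count tables return p = 1
with a warning rather than NaN.

## Known limitations

Published cohort-level headline numbers (median TMB, mean GII, the exact
15-gene list, AUC 0.89) depend on restricted-access patient data and are
not reproducible from synthetic cohorts; the package instead verifies
every computable worked example and the calibration of each statistic
against known truth. dN/dS here uses shared context rates without
per-gene covariates — simpler than full covariate models, identifiable at
panel scale, but not a re-implementation of them. The persistence
statistic follows the printed rate-ratio formula, which differs from the
odds ratio its surrounding text names; both are reported.
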