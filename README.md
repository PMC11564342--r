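# adenomaevo

Somatic-mutation analysis for targeted panel sequencing of colorectal
adenoma (CRA) tissue and matched plasma cell-free DNA (cfDNA), aimed at
the question behind early colorectal-cancer screening: which genomic
features of a premalignant lesion can be read from tissue, which survive
into plasma, and which separate adenoma from carcinoma.

The package implements, as tested reusable functions:

* **Consensus variant filtering** — merge calls from multiple somatic
  callers on normalized variant keys; keep tissue variants seen by ≥ 2
  callers, plasma variants with matched-normal VAF = 0 (single-caller
  plasma calls need VAF ≥ 0.05); remove variants with population AF
  > 0.01, mappability < 0.75, or same-sample neighbours within 100 bp.
* **Tumor-informed plasma rescue** — for each tissue mutation, a
  one-sided Fisher exact test of cfDNA vs control pileup counts;
  detection requires BH q ≤ 0.1, cfDNA VAF ≥ 2× control VAF, and ≥ 4 alt
  reads.
* **Burden metrics** — TMB (mutations per Mb of panel, default 3.34 Mb)
  and GII, the fraction of the segmented genome in gain, loss or
  copy-neutral LOH.
* **Clonal evolution** — the 1/f neutrality statistic (fit of the
  cumulative subclonal count M(f) against 1/f − 1/f_max through the
  origin; neutral iff R² ≥ 0.98 on VAFs in (0.1, 0.25)) and
  trinucleotide-context dN/dS with exact Poisson CIs, globally, by
  clonality (VAF ≥ 0.25 vs below), and per gene.
* **Cohort statistics** — per-gene and per-pathway Fisher comparisons
  between cohorts, the polyp-persistence rate ratio
  R_i = (m_i/n_i)/(M/N), and one-sided binomial enrichment.
* **CRA-vs-CRC classifier** — a random forest on the binary gene×patient
  matrix with minimal-depth variable selection (permutation-null
  threshold by default), evaluated by rank AUC, AUCPR and OOB error.
* **Synthetic data** — generators for every input above with known
  ground truth: multi-caller call sets with planted artifacts, plasma
  pileups with shedding at VAF ≈ 1–3%, segment plans hitting a target
  GII, 1/f VAF spectra, selected coding mutations, cohort matrices.

## Worked example

Simulate a full input set, run the pipeline, and look at the plasma
rescue stage:

```r
library(adenomaevo)

dir <- tempfile()
cfg <- sim_config(seed = 7)
run_yaml <- simulate_pipeline_inputs(cfg, dir)
res <- run_pipeline(run_yaml)
res$status
#>       stage status message
#> 1    filter     ok
#> 2    rescue     ok
#> 3    burden     ok
#> 4 evolution     ok
#> 5    cohort     ok
#> 6  classify     ok

# tumor-informed rescue on simulated plasma counts
ps <- simulate_plasma_counts(cfg, n_shed = 10, n_unshed = 10)
rr <- rescue(data.frame(patient_id = "P1", key = ps$truth$key), ps$counts)
sum(rr$detected); sum(ps$truth$shed)
#> [1] 10
#> [1] 10

# neutrality statistic on a synthetic neutral spectrum
print(neutrality_test(simulate_neutral_vafs(cfg, n = 1000)))
#> neutrality fit: R^2 = 0.9970 (threshold 0.98) -> neutral
#>   slope mu/beta = 167.15 over 928 subclonal mutations in (0.1, 0.25)
```

All ten shed variants are recovered (the remaining ten, without tumor
DNA in plasma, stay undetected), and a 1000-mutation neutral spectrum
with 1000× binomial read noise classifies as neutrally evolved.

A worked plasma-cohort summary from the shipped example table of
plasma-detected mutations in an 85-patient adenoma cohort:

```r
tab <- read.delim(system.file("extdata", "cra_plasma_detected_mutations.tsv",
                              package = "adenomaevo"))
s <- cohort_detection_summary(tab, n_patients = 85)
s$detection_rate_pct   # 5.9  (5 of 85 patients)
s$n_mutations          # 7
```

## Documentation

The methods vignette (`vignettes/adenoma-cfdna-methods.Rmd`) describes
the statistical models, default thresholds and their rationale, what the
synthetic generators do and do not emulate, and known limitations.
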