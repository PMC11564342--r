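Package: adenomaevo
Title: Somatic Mutation Pipeline for Colorectal Adenoma Tissue and Plasma Panel Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted panel sequencing of colorectal
    adenoma (CRA) tissue and matched plasma cell-free DNA. Implements
    multi-caller somatic consensus and quality filtering, tumor-informed
    plasma mutation rescue (per-site one-sided Fisher tests with
    Benjamini-Hochberg correction), tumor mutational burden and genome
    instability index from allele-specific copy-number segments, clonal
    evolution statistics (1/f neutrality R-squared and context-aware dN/dS
    selection estimation), cohort-level gene and pathway frequency
    comparisons including a polyp-persistence risk statistic, and a random
    forest adenoma-versus-carcinoma classifier with minimal-depth variable
    selection. A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
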