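Package: aquaGS
Title: Single-Step Genomic Evaluation, Imputation and Genotyping-Cost
    Modelling for Aquaculture Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-step genomic best linear unbiased prediction
    (ssGBLUP) in fish breeding nuclei: pedigree (A), genomic (G) and
    combined (H-inverse) relationship matrices, AI-REML variance-component
    estimation for an animal model with a full-sib common-environment
    effect, weighted-ssGBLUP window-based association analysis, in-silico
    low-density SNP panel design by linkage-disequilibrium pruning,
    family-plus-population genotype imputation, cross-validated prediction
    accuracy, and genotyping cost scenarios. Includes a gene-dropping
    simulator of multi-generation full/half-sib populations with linkage
    disequilibrium so every stage can be exercised and verified at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
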