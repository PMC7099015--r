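Package: strataprs
Title: Fine-Scale Population Structure and Polygenic Score Stratification Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying how fine-scale
    population structure biases polygenic risk score (PRS) prediction within a
    nominally homogeneous cohort. Provides a Balding-Nichols island-model
    cohort simulator (hierarchical drift, additive polygenic traits with
    per-subpopulation environmental offsets, liability-threshold binary
    traits), PLINK bed/bim/fam input and output, variant and relatedness
    quality control (exact Hardy-Weinberg test, LD pruning, method-of-moments
    PI_HAT), genotype principal component analysis with embedding adapters and
    Cohen's kappa cluster correspondence, covariate-adjusted association
    scans, clumping-and-thresholding PRS construction with rank-inverse-normal
    scoring, Haseman-Elston heritability regression, and the per-trait
    delta-normalized-PRS, delta-normalized-phenotype, BIAS, and
    confounder-correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    uwot,
    Rtsne
Config/testthat/edition: 3
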