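Package: vprotqtl
Title: Quantitative Genetics of Cell-to-Cell Protein Expression Variability
Version: 0.1.0
Authors@R: person("vprotqtl", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for mapping the genetic basis of cell-to-cell
    protein expression variability from single-cell flow cytometry data.
    Provides flow-cytometry event preprocessing (event QC, biexponential
    transform, landmark normalization, doublet removal, rectangular gating,
    cell-volume normalization), a mean-adjusted expression-noise statistic
    (standardized residuals of CV-squared from a local polynomial fit on mean
    expression), ACE twin variance decomposition with bootstrap standard
    errors and zygosity-permutation p-values, linear mixed model QTL scans
    with leave-one-chromosome-out genetic relationship matrices, cis window
    permutation adjustment via a beta approximation, LD clumping, varSNP
    annotation and TSS-proximity enrichment, and two-sample Mendelian
    randomization (Wald ratio, maximum likelihood, IVW, MR-Egger, Cochran's
    Q). A synthetic-data generator with known ground truth (LD-structured
    genotypes, MZ/DZ twin cohorts, latent per-individual expression
    parameters, single-cell event tables with doublets, and causal
    exposure-outcome chains) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
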