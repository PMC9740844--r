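Package: muscleomics
Title: Spectral-Count Differential Proteomics and Targeted Metabolomics
    Statistics for Two-Group Muscle Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for two-group skeletal-muscle multi-omics
    designs built on pooled label-free proteomics and targeted amino-acid /
    acylcarnitine metabolomics. Implements identification filtering and the
    spectral-count log-ratio statistic (Rsc) with zero-count correction,
    over-representation analysis of protein subsets by one-sided Fisher's
    exact test with Benjamini-Hochberg false-discovery control over GMT
    annotation sets, and a metabolite-panel statistics suite: protein-content
    normalised concentrations, log10 transform with Pareto scaling, NIPALS
    PLS-DA with variable-importance-in-projection (VIP) scores,
    normality-gated univariate testing (Welch t or Mann-Whitney, gated by the
    D'Agostino-Pearson omnibus test), volcano classification and Euclidean
    hierarchical clustering. Includes seeded synthetic-data generators with
    planted effects so every stage is testable without raw mass-spectrometry
    data, plus a YAML-configured end-to-end driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
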