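Package: noisefit
Title: Expression Noise, Competitive Fitness and Individual-Based Growth
    Simulation for Single-Gene Reporter Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how cell-to-cell variability (expression
    noise) in the activity of a single promoter affects competitive fitness
    in budding yeast. Implements flow-cytometry event processing (quantile
    and density gating, PCA-based size normalisation, log-log
    fluorescence-to-mRNA calibration, batch and autofluorescence
    correction, MAD replicate filtering), competitive-fitness estimation
    from two-colour cell counts with Hardy-Weinberg-style doublet
    correction and from pyrosequencing allele-frequency trajectories,
    promoter copy-number inference from pyrogram peak heights,
    residual-based analysis of the noise-fitness relationship (local
    regression, expression-optimum classification, permutation tests,
    robustness grids), an individual-based stochastic simulator linking
    single-cell expression levels to population growth, simulation-based
    power analysis for serial-dilution competition assays, and
    synthetic-data generators with known ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
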