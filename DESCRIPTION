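Package: phenotray
Title: Tray-Image Phenotyping, Growth-Curve Traits and Phenotypic Selection
    Under Factorial Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for factorial heat-by-drought stress
    experiments on rosette plants grown in multipot trays: colour-range
    segmentation of top-view tray images into per-pot rosette areas,
    nonlinear growth-curve fitting with AIC model selection across seven
    candidate models, extraction of growth traits (asymptotic size, time to
    inflection, maximal growth rate), leaf and root functional traits (SLA,
    LDMC, root:shoot ratio) with nuisance-effect correction, Lande-Arnold
    phenotypic selection analysis with within-treatment standardization and
    a family-mean imputation rule for the combined-stress treatment, and
    descriptive population statistics (rank-sum contrasts, per-treatment
    correlations, PCA, factorial effect estimates). A synthetic-data
    generator produces complete experiments (design, growth series, tray
    images, harvest weights, fitness) with known ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    png,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
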