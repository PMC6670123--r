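Package: octarcd
Title: Retinal Capillary Density Quantification from OCT Angiography
Version: 0.1.0
Authors@R:
    person("octarcd", "maintainers", email = "octarcd@example.org",
           role = c("aut", "cre"))
Description: Quantifies retinal capillary density (RCD) from en-face optical
    coherence tomography angiography (OCT-A) images of the macula. The
    pipeline upsamples 3 x 3 mm fovea-centered angiograms by bicubic
    interpolation, detects the foveal avascular zone (FAZ) with a combined
    Canny edge / level-set segmentation, binarizes the vasculature with a
    noise-baseline global threshold (large vessels) and a local-mean adaptive
    threshold (all vessels), subtracts the two maps to isolate capillaries,
    and reports RCD over a 2.5 mm macular zone excluding a fixed 0.6 mm
    foveal disc. Companion modules simulate OCT-A-like phantoms with known
    ground truth and three-group clinical cohorts (healthy controls,
    diabetics without retinopathy, diabetics with mild retinopathy), and
    provide the cohort statistics layer: Pearson chi-square, pooled t from
    summary statistics, one-way ANOVA, risk-factor dichotomization and
    subgroup reports, and multiple linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
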