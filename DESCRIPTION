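Package: treecomplexity
Title: Structural Complexity of Individual Trees from Laser Scanning Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional structural
    complexity of individual trees from terrestrial laser scanning (TLS)
    point clouds. Provides point-cloud input/output and height
    normalization, a synthetic stand generator for even-aged conifer
    plots under different thinning treatments, canopy-height-model based
    individual-tree segmentation (variable window filter tree tops and
    marker-controlled watershed), stem/crown point classification with
    taper-curve stem modelling, convex-hull crown metrics, the
    box-counting fractal dimension as a scale-independent complexity
    measure, the Hegyi distance-dependent competition index, and a
    nested two-level mixed-effects analysis layer for treatment
    comparisons (ANOVA, Tukey contrasts, per-treatment correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pbkrtest,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
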