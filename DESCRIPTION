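Package: glocoh
Title: Global Coherence of Discourse and Its Neural Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scores the global coherence of timed speech transcripts against
    prototype topic vectors in a latent semantic analysis space, converts the
    scores into block-wise parametric modulators for first-level fMRI general
    linear models, and relates the fitted coherence effects to a principal
    connectivity gradient (decile binning plus linear mixed models with
    quadratic trends) and to default-mode, semantic-control, and
    multiple-demand network masks (top-voxel selection, repeated-measures
    ANOVA with Holm-adjusted post hoc tests, and an individual-differences
    covariate analysis). A synthetic-data generator produces topic-driven
    transcripts, connectivity gradients, network masks, and BOLD time series
    with known ground truth so the full pipeline is testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
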