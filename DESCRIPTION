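Package: hdrsynth
Title: Quantitative Synthesis of Heterogeneity-Diversity Relationships
Version: 0.1.0
Authors@R:
    person("Reef", "Synthesis Lab", email = "hdrsynth@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesising heterogeneity-diversity relationships
    (HDRs) from multi-study rocky-reef data. Standardises heterogeneity
    gradients measured in incompatible units to a common 0-1 scale, computes
    per-observation log response ratio (lnRR) effect sizes against the
    lowest-heterogeneity baseline of each within-study HDR group, and fits
    quadratic linear mixed-effects models with study-level random slopes and
    plot-level intercepts. Includes model batteries across heterogeneity
    facets, organismal groups, ecological processes and environmental
    moderators; shape classification of fitted dose-response curves;
    sensitivity analyses under published exclusion rules; publication-bias
    diagnostics; and a synthetic multi-study data generator with known truth
    for simulation-based parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
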