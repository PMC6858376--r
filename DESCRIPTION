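Package: staphycurve
Title: Foveal Curvature Metrics for Posterior Staphyloma from OCT RPE Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the steepness of the foveal curvature within a
    posterior staphyloma from retinal pigment epithelium (RPE) depth
    profiles traced on fovea-centred OCT B-scans. Implements axial-length
    magnification correction, staphyloma heights at 3 mm from the fovea,
    the least-squares quadratic coefficient on a 300-um sampling grid, and
    the arc-length/chord curvature index, together with study eligibility
    screening (high-myopia criteria, dome-shaped macula rule, one eye per
    patient), seeded synthetic cohort generators at the metric and
    geometry level, and the group-comparison statistical layer (one-way
    ANOVA with Bonferroni post-hoc t-tests, chi-square tests, and
    correlation analyses) producing tidy comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
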