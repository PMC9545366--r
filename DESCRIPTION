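Package: hipshapes
Title: Statistical Shape Modeling of the Proximal Femur and Hip Osteoarthritis Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional statistical shape modeling of the proximal
    femur from 85-point landmark outlines. Provides generalized Procrustes
    alignment and principal-component hip shape modes, automated geometric
    morphometrics (alpha angle, lateral centre-edge angle, neck-shaft angle,
    narrowest neck width, minimum joint-space width), radiographic hip
    osteoarthritis grading from osteophyte areas and joint-space narrowing,
    per-mode logistic and Cox proportional-hazards association models with
    Bonferroni control and attenuation summaries, composite risk-shape
    reconstruction, and a seeded synthetic cohort generator that emulates the
    landmark, covariate and outcome structure the analysis assumes.
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
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
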