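Package: urbangrad
Title: Urban-Gradient Location-Scale Analysis of Well-Being Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the mean and the spread of survey
    outcomes vary along a continuous urban-rural gradient. Urbanicity is
    measured as the distance from a residence to the nearest city center
    divided by the square root of that city's population. Outcomes are
    modelled with penalized B-spline location-and-scale regression (a
    GAMLSS-type model with smooth mean and smooth log-SD), optimal
    distances and effect sizes are extracted from the fitted gradients,
    and a seeded synthetic-cohort generator emulates the survey structure
    (Likert items, a binary loneliness item, banded household income) so
    the whole pipeline can be exercised and validated without restricted
    data. Robustness variants (minimum city size, largest-city exclusion,
    covariate adjustment, radius normalization, participation weights,
    population density) are driven from a single run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    ggplot2,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
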