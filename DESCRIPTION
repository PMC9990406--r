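Package: amuplan
Title: Farm-Specific Antimicrobial Usage Reduction Plans from Biosecurity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating farm biosecurity practices to
    antimicrobial usage (AMU, measured as treatment incidence in DDDvet per
    1000 animal-days) in broiler farms sampled across several countries.
    Fits a mixed-effects random forest with a country-level random
    intercept, selects predictors by cross-validated recursive feature
    elimination on Gini importance, clusters farms on the forest proximity
    matrix with class prototypes, estimates per-measure effect sizes by
    partial dependence with bootstrap confidence intervals, and enumerates
    farm-specific intervention scenarios with yearly costs and
    cost-effectiveness per unit of AMU reduction. Includes a synthetic farm
    data generator with planted effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
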