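Package: thermopair
Title: Thermal Requirements of Insects and Paired Invasive/Non-Invasive Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates insect thermal requirements (the lower developmental
    threshold, LDT, and the sum of effective temperatures, SET) from
    development-time by temperature rearing data via the linear
    rate-temperature model, assembles taxonomically matched pairs of invasive
    and non-invasive species from the same continent, and runs the paired
    comparative inference: t-tests, linear mixed models with taxonomic random
    effects and Satterthwaite degrees of freedom, intraclass correlations from
    variance components, likelihood-ratio sequences over nested random-effect
    structures, and the correlation of paired LDT and SET differences.
    Includes single-sine degree-day accumulation for phenology prediction and
    a seeded synthetic-data generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
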