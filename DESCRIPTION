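Package: rotanutri
Title: Whole-Rotation Calorie and Macronutrient Outputs of Crop Rotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts crop yields from long-term rotation experiments into
    human-available calories and macronutrients (carbohydrates, proteins,
    fats) under alternative forage end uses (milk, beef, biofuel),
    classifies rotations by crop functional richness, screens and gap-fills
    yield records, fits linear mixed models of square-root-transformed
    whole-rotation outputs against functional richness and time with
    crossed random effects for site, group-in-site and calendar year, and
    evaluates dietary macronutrient balance against recommended intake
    ranges. Includes a synthetic long-term-experiment generator with known
    ground truth for parameter-recovery testing, multiplicity-adjusted
    contrasts, marginal and conditional R-squared, and a
    leave-one-site-out sensitivity loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
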