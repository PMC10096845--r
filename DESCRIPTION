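Package: dietmod
Title: Isocaloric Removal Modeling of Meat and Poultry in Healthy Dietary Patterns
Version: 0.1.0
Authors@R: person("dietmod", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Dietary-pattern modeling of the nutritional impact of removing a
    3 oz (85 g) serving of meat or poultry from 2000 kcal Healthy Dietary
    Patterns. Builds composite nutrient profiles as nested population-weighted
    convex blends, estimates blend proportions from survey-weighted dietary
    recall records, applies isocaloric renormalization after serving removal,
    flags nutrient changes of 10% or more from baseline, and reproduces the
    published modified and isocaloric nutrient tables cell by cell from the
    packaged composite and baseline fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
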