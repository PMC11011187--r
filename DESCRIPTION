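Package: feedeval
Title: Feed Evaluation by Difference-Method Digestibility Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating feed ingredients from metabolic-cage
    digestibility trials. Computes apparent digestibility coefficients from
    intake/feces mass balance, recovers test-ingredient digestibility from
    mixed diets by the difference (indirect) method, estimates digestible
    nutrients, total digestible nutrients (TDN), digestible and metabolizable
    energy, blends diet formulations, summarises voluntary intake on a live
    weight and metabolic weight (W^0.75) basis, and compares treatments with
    one-way ANOVA and Duncan's multiple range test with compact letter
    display. Includes a seeded simulator of metabolic-cage trials with known
    ground truth for validating the full analysis chain, and bundled summary
    data from a guinea-pig evaluation of bovine slaughterhouse by-product
    meals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
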