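Package: upfscan
Title: Identify Ultra-Processed Foods from Package Label Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens packaged-food catalogs for ultra-processed food
    products (NOVA group 4) using only information printed on labels:
    cosmetic food additives detected in the ingredient list via a
    user-extensible functional lexicon, and critical nutrients in excess
    under the Pan American Health Organization nutrient profile model
    (free sugars, sodium, total fat, saturated fat, trans fat,
    sweeteners).  Combines the two criteria into a single screening
    flag, validates agreement against reference NOVA classifications
    with Cohen's kappa, reconstructs 2x2 agreement tables from published
    marginal summaries, tabulates flag frequencies by NOVA group and
    subgroup, and generates seeded synthetic label catalogs with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
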