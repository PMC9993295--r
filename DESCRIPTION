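Package: allodose
Title: Allometric Scaling of Adult Antiretroviral Doses to Children
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scales adult drug doses to paediatric values with the
    allometric three-quarter power model, derives weight-band dosing
    tables from a scaling model and a tablet formulary (the
    abacavir/lamivudine 120/60 mg dispersible fixed-dose combination by
    default), and compares dosing strategies -- WHO-style weight bands
    versus allometric scaling with formulary rounding -- on real or
    synthetic paediatric cohorts using a rank-sum test and age-weight
    correlation. Includes a truncated-normal synthetic cohort generator
    calibrated to published per-age weight summaries, cohort file I/O
    with validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
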