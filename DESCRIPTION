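Package: vegfpv
Title: Pharmacovigilance Analysis of VEGF/VEGFR-Inhibitor-Induced Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality signal detection (reporting odds ratio and
    information component), time-to-onset comparison, blood-pressure category
    transition accounting, and pan-cancer pathway-activity correlation for
    spontaneous adverse-event reports on VEGF and VEGFR inhibitors. Includes
    readers for the FAERS quarterly ASCII layout and a simplified CSV dialect,
    the preprocessing chain (deduplication, malignancy-indication filtering,
    drug-class assignment), single-sample gene-set enrichment scoring, and
    seeded synthetic-data generators that emulate every input with recorded
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
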