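Package: zfmea
Title: Z-Number FMEA Risk Prioritization with Z-SWARA, Z-WASPAS and
    Super-Efficiency DEA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid multi-criteria risk prioritization for drug supply
    chains from expert Z-number assessments. Implements triangular fuzzy
    arithmetic with Z-number reliability weighting, fuzzy risk priority
    numbers (FMEA), stepwise criterion weighting (Z-SWARA), weighted
    aggregated sum-product ranking (Z-WASPAS), input-oriented
    super-efficiency data envelopment analysis under variable returns to
    scale, and an equal-weight hybrid score combining the three views per
    objective and across objectives. Ships the published 21-failure-mode
    antiretroviral supply-chain case study as plain-text fixtures and a
    synthetic expert-panel generator for testing and demonstration.
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
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
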