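Package: taxshift
Title: Tobacco Tax Pass-Through Analysis by Cigarette Price Segment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how tobacco excise increases are passed
    through to retail cigarette prices. Computes per-pack tax burdens under a
    dated mixed excise structure (specific duty, ad valorem duty, VAT),
    builds segment-level weighted average prices and net-of-tax revenues from
    brand-level semiannual panels, deflates them against a consumer price
    index, classifies over- and undershifting of duty increases across price
    segments and half-year windows, compares most-popular-price-category and
    weighted-average price indices, and examines brand-level associations
    between price changes and market share. A synthetic market generator with
    known ground-truth pass-through makes every pipeline stage testable
    without proprietary scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
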