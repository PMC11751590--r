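Package: dendrodate
Title: Cross-Dating, Missing-Ring Detection and Age Determination for
    Slow-Growing Shrub Ring-Width Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dendrochronological age determination of
    slow-growing woody plants such as tundra junipers: Tucson decadal
    (.rwl) and long-table input/output of ring-width series, high-pass
    indexing, the classical cross-dating statistics (Gleichlaeufigkeit,
    overlap correlation, Baillie-Pilcher t-value), sliding calendar
    placement against a reference, statistical detection and insertion of
    locally absent (missing) rings, robust biweight mean chronologies with
    rbar/EPS diagnostics, an end-to-end dating pipeline from multiple
    measured radii per disk to per-sample age reports and per-site
    summaries, and a synthetic ring-width population generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
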