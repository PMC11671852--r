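Package: firerecov
Title: Post-Fire Vegetation Recovery Rates from Satellite Greenness Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-pixel post-fire vegetation recovery rates from
    gridded vegetation-index (EVI) time series. Implements an ideal-seasonal-cycle
    ("Gorgeous Year") normalization, exponential greenness-recovery fitting by
    log-linear regression over adaptive 2-5 year windows, fire-recurrence
    filtering of burned-area records, and modulation analyses relating recovery
    rate to fire severity, pre-fire greenness and post-fire seasonal climate
    anomalies. Ships a synthetic-scene generator with a known-truth ledger so the
    whole pipeline can be validated end-to-end against injected parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
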