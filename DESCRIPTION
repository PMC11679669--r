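Package: imep
Title: Force-Platform Balance Scoring for Primary-School Children (IMEP)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the IMEP (Instrument for the Measurement of Balance in
    Primary Education) scoring pipeline for static and dynamic balance tests in
    children aged 6 to 9: reading force-plate text exports and marker-trajectory
    tracks, bandpass filtering and RMS summaries of plate channels, center-of-
    pressure path and 95% ellipse area, marker-based movement quantification,
    and the published 1-10 scoring scales for the single-leg balance (SLB),
    tandem balance (TBT), and Y balance (YBT) tests. Also provides a scale
    builder that re-derives the full scale (inversion constant, demographic
    correction regression, adjusted-score range) on any cohort, and a synthetic
    cohort and sway-trial generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
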