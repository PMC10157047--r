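Package: erpselect
Title: ERP Feature Extraction and Exhaustive-Subset Regression for Trait Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking event-related potential (ERP) measures of visual
    motion processing to continuous trait scores. Provides a synthetic EEG
    generator with trait-modulated N170/P200 components and injectable blink
    artifacts, a deterministic ERP pipeline (zero-phase band-pass filtering,
    epoching, baseline correction, peak-to-peak artifact rejection, averaging,
    windowed peak detection, feature-table assembly), and an exhaustive
    best-subset multiple regression engine scored by leave-one-out
    cross-validated mean absolute error, with standardized coefficients,
    selection frequencies and weight-diagram output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
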