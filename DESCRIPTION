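Package: riemerp
Title: Riemannian Minimum-Distance-to-Mean Decoding of P300 Event-Related
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Offline decoding pipeline for oddball brain-computer
    interfaces (BCI). Single-trial EEG epochs are augmented with averaged
    target and non-target prototypes, summarised as super-trial covariance
    matrices, and classified by minimum Riemannian distance to per-class
    geometric (Karcher) mean covariances.  A stepwise linear discriminant
    analysis (SWLDA) baseline, a synthetic spatial-oddball EEG simulator,
    an evaluation protocol reporting command accuracy against the number
    of averaged ERPs with rank-sum comparisons, and European Data Format
    (EDF) input/output are included.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
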