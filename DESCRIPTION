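Package: cochleaR
Title: Cochlear-Inspired Features and Classification for Animal Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gammatone-filterbank (ERB-scale) auditory feature extraction for
    bioacoustic species classification. Provides audio preprocessing (WAV
    loading, band-limited resampling to 11025 Hz, 20 Hz high-pass, 50
    percent-overlap framing, energy-based silence removal), cochlear features
    (gammatone filter output energies, log-energy DCT coefficients, delta
    vectors, per-vocalization aggregates), scalar vocalization features
    (duration, active-frame rate, active-frequency interval), a mel-scale
    triangular filterbank baseline, a small feed-forward network classifier
    trained with a quasi-Newton solver, frame-group majority voting, a
    dual-network agreement/rejection architecture, an evaluation harness with
    repeated stratified splits, and a deterministic synthetic vocalization
    generator so the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
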