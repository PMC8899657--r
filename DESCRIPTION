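Package: oprars
Title: Hearing-Aid Fitting by Genetic Random Search over Insertion Gains
    and Compression Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prescribing and optimizing multichannel hearing-aid
    settings with seeded genetic random-search algorithms. Implements a
    five-channel dynamic-range-compression hearing-aid simulator, a
    loudness-recruitment hearing-loss simulator, a band-audibility Speech
    Intelligibility Index, compression-ratio constraint enforcement with
    SII-based audibility equalization, a surrogate speech-intelligibility
    objective with an external-recognizer adapter, and three random-search
    strategies with decaying search ranges for tuning per-channel insertion
    gains and compression thresholds against an audiogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
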