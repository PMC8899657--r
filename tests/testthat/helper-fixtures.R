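## Shared fixture builders. Everything is generated in code at test time.

FS <- 16000

flat_audiogram <- function(hl, label = "flat") {
  audiogram(thresholds_db_hl = rep(hl, 11), label = label)
}

## Steady tone as a calibrated signal at a given long-term level.
tone_signal <- function(freq_hz, level_db_spl, dur_s = 0.5, fs = FS) {
  x <- calibrated_signal(sin(2 * pi * freq_hz * seq_len(round(dur_s * fs)) / fs), fs)
  set_level(x, level_db_spl)
}

## Long-term level of the second half of a signal (after compressor settling).
settled_level <- function(x) {
  n <- length(x$samples)
  rms_level(calibrated_signal(x$samples[seq(floor(n / 2), n)], x$sample_rate_hz,
                              x$ref_db_spl))
}

## A small token set shared across tests (built once per test run).
small_tokens <- local({
  cache <- NULL
  function(n = 8, seed = 42) {
    if (is.null(cache)) cache <<- generate_tokens(n, seed)
    cache
  }
})

## A flat 55-dB SPL speech band spectrum for SII-based tests.
speech_spectrum_flat <- function(level = 55) {
  band_spectrum(rep(level, 6), "octave")
}
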