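## Speech Intelligibility Index: band-audibility scheme over octave or
## third-octave bands, with importance weights and equivalent-internal-noise
## levels tabulated in inst/extdata (values per ANSI S3.5; the octave
## internal-noise levels are the published third-octave spectrum integrated
## over the octave bandwidth).

.sii_tables <- new.env(parent = emptyenv())

sii_band_table <- function(scheme = c("octave", "third-octave")) {
  scheme <- match.arg(scheme)
  key <- gsub("-", "_", scheme)
  if (!exists(key, envir = .sii_tables, inherits = FALSE)) {
    path <- system.file("extdata", sprintf("sii_%s_bands.csv", key),
                        package = "oprars", mustWork = TRUE)
    tab <- read.csv(path)
    tab$importance <- tab$importance / sum(tab$importance)
    assign(key, tab, envir = .sii_tables)
  }
  get(key, envir = .sii_tables)
}

#' Band spectrum
#'
#' Per-band sound levels under a band scheme ("octave": 6 bands 250--8000 Hz;
#' "third-octave": 18 bands 160--8000 Hz).
#'
#' @param level_db_spl Band levels in dB SPL (`-Inf` allowed for silence).
#' @param scheme Band scheme identifier.
#' @param center_hz Band centre frequencies; default: the scheme's centres.
#' @return An object of class `band_spectrum`.
#' @export
band_spectrum <- function(level_db_spl, scheme = "octave",
                          center_hz = sii_band_table(scheme)$center_hz) {
  tab <- sii_band_table(scheme)
  if (length(center_hz) != nrow(tab) || any(center_hz != tab$center_hz)) {
    stop("band centers must match the chosen scheme", call. = FALSE)
  }
  if (length(level_db_spl) != length(center_hz) || anyNA(level_db_spl)) {
    stop("one finite (or -Inf) level per band is required", call. = FALSE)
  }
  structure(list(center_hz = center_hz,
                 level_db_spl = as.numeric(level_db_spl),
                 scheme = scheme),
            class = "band_spectrum")
}

#' Per-band audibility
#'
#' Audibility of speech in each band: `(speech - disturbance + 15) / 30`,
#' clipped to \[0, 1\]. The disturbance is the listener's threshold-equivalent
#' band level in dB SPL.
#'
#' @param speech,threshold [band_spectrum()] objects on the same scheme
#'   (speech band levels and threshold-equivalent disturbance levels).
#' @return Numeric vector of audibilities in \[0, 1\], one per band.
#' @export
band_audibility <- function(speech, threshold) {
  stopifnot(inherits(speech, "band_spectrum"), inherits(threshold, "band_spectrum"))
  if (!identical(speech$scheme, threshold$scheme)) {
    stop("incompatible spectra: band schemes differ", call. = FALSE)
  }
  clamp((speech$level_db_spl - threshold$level_db_spl + 15) / 30, 0, 1)
}

## Threshold-equivalent disturbance spectrum for a listener: hearing level
## interpolated at the band centres plus the band's equivalent internal
## noise level (the normal-hearing reference).
audiogram_band_disturbance <- function(a, scheme = "octave") {
  stopifnot(inherits(a, "audiogram"))
  if (!is_complete_audiogram(a)) {
    stop("complete audiogram required", call. = FALSE)
  }
  tab <- sii_band_table(scheme)
  hl <- interp_log2(a$frequencies_hz, a$thresholds_db_hl, tab$center_hz)
  band_spectrum(hl + tab$internal_noise_db, scheme = scheme)
}

#' Speech Intelligibility Index
#'
#' Importance-weighted sum of band audibilities: `sum(I_b * A_b)` with the
#' scheme's importance weights `I_b` summing to 1. No masking-spread or
#' high-level distortion terms are modelled (speech-in-quiet use).
#'
#' @param speech A [band_spectrum()] of speech levels in dB SPL.
#' @param a A complete [audiogram()].
#' @return SII value in \[0, 1\].
#' @export
#' @examples
#' s <- band_spectrum(rep(80, 6), "octave")
#' sii_value(s, audiogram(thresholds_db_hl = rep(0, 11)))
sii_value <- function(speech, a) {
  stopifnot(inherits(speech, "band_spectrum"))
  tab <- sii_band_table(speech$scheme)
  aud <- band_audibility(speech, audiogram_band_disturbance(a, speech$scheme))
  if (anyNA(aud)) stop("SII failure: non-finite audibility", call. = FALSE)
  sum(tab$importance * aud)
}

#' Band spectrum of a calibrated signal
#'
#' Long-term RMS band levels in dB SPL, measured from the periodogram of the
#' signal under its calibration (full-scale reference). Digital silence in a
#' band yields a `-Inf` sentinel level.
#'
#' @param x A [calibrated_signal()].
#' @param scheme Band scheme identifier (see [band_spectrum()]).
#' @return A [band_spectrum()].
#' @export
spectrum_of_signal <- function(x, scheme = "octave") {
  stopifnot(inherits(x, "calibrated_signal"))
  if (length(x$samples) == 0) stop("invalid input: empty signal", call. = FALSE)
  tab <- sii_band_table(scheme)
  half_bw <- if (scheme == "octave") sqrt(2) else 2^(1 / 6)
  n <- length(x$samples)
  spec <- fft(x$samples)
  ## one-sided mean-square power per bin
  p <- (Mod(spec)^2) / n^2
  nh <- floor(n / 2)
  p1 <- p[seq_len(nh + 1)]
  if (nh >= 1) p1[2:(nh + if (n %% 2 == 0) 0 else 1)] <-
      2 * p1[2:(nh + if (n %% 2 == 0) 0 else 1)]
  freqs <- (seq_len(nh + 1) - 1) * x$sample_rate_hz / n
  lev <- vapply(seq_len(nrow(tab)), function(b) {
    lo <- tab$center_hz[b] / half_bw
    hi <- tab$center_hz[b] * half_bw
    pw <- sum(p1[freqs >= lo & freqs < hi])
    if (pw > 0) 10 * log10(pw) + x$ref_db_spl else -Inf
  }, numeric(1))
  band_spectrum(lev, scheme = scheme)
}

## SII of a prescription applied to a measured clean-speech spectrum: the
## insertion-gain function (65-dB SPL level), interpolated at the band
## centres, is added to the clean band levels. Slow compression makes the
## gain quasi-static at the operating point, so this band-domain application
## matches the long-term spectrum of the amplified waveform.
sii_of_prescription <- function(p, speech_spectrum, a, offset_db = 0) {
  stopifnot(inherits(p, "prescription"), inherits(speech_spectrum, "band_spectrum"))
  ig <- interp_log2(p$frequencies_hz, p$ig_sp65, speech_spectrum$center_hz)
  amp <- band_spectrum(speech_spectrum$level_db_spl + ig + offset_db,
                       scheme = speech_spectrum$scheme)
  sii_value(amp, a)
}
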