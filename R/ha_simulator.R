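#' Calibrated audio signal
#'
#' A mono waveform together with its sample rate and full-scale calibration:
#' `ref_db_spl` is the sound pressure level corresponding to unit RMS. All
#' simulator stages preserve this calibration.
#'
#' @param samples Numeric waveform samples.
#' @param sample_rate_hz Sample rate in Hz; must be at least 16 kHz (the top
#'   channel edge is 8 kHz).
#' @param ref_db_spl dB SPL of a unit-RMS signal (default 100).
#' @return An object of class `calibrated_signal`.
#' @export
calibrated_signal <- function(samples, sample_rate_hz, ref_db_spl = 100) {
  samples <- as.numeric(samples)
  if (sample_rate_hz < 16000) {
    stop("undersampled: sample rate must be >= 16 kHz", call. = FALSE)
  }
  if (!is.finite(ref_db_spl)) stop("calibration reference must be finite", call. = FALSE)
  structure(list(samples = samples,
                 sample_rate_hz = sample_rate_hz,
                 ref_db_spl = ref_db_spl),
            class = "calibrated_signal")
}

#' Long-term RMS level of a calibrated signal
#'
#' @param x A [calibrated_signal()].
#' @return Level in dB SPL (`-Inf` for digital silence).
#' @export
rms_level <- function(x) {
  stopifnot(inherits(x, "calibrated_signal"))
  ms <- mean(x$samples^2)
  if (ms <= 0) return(-Inf)
  10 * log10(ms) + x$ref_db_spl
}

#' Scale a calibrated signal to a target long-term level
#'
#' @param x A [calibrated_signal()].
#' @param target_db_spl Desired long-term RMS level in dB SPL.
#' @return The rescaled [calibrated_signal()].
#' @export
set_level <- function(x, target_db_spl) {
  lev <- rms_level(x)
  if (!is.finite(lev)) stop("cannot set the level of digital silence", call. = FALSE)
  x$samples <- x$samples * db_to_lin(target_db_spl - lev)
  x
}

## One-pole smoothing coefficient for a time constant in ms at rate fs.
smoothing_alpha <- function(tau_ms, fs) 1 - exp(-1000 / (tau_ms * fs))

## Mean power per non-overlapping block of `block` samples (column-wise for
## matrices). The tail is padded by repeating the last sample.
block_power <- function(x, block) {
  x <- as.matrix(x)
  n <- nrow(x)
  nb <- ceiling(n / block)
  if (nb * block > n) x <- rbind(x, x[rep(n, nb * block - n), , drop = FALSE])
  p <- x^2
  dim(p) <- c(block, nb, ncol(x))
  colMeans(p)
}

## Contiguous band splitting by a zero-phase crossover tree. At each inner
## edge a Butterworth low-pass/high-pass pair with a common cutoff is
## applied forward-backward: the two zero-phase responses are exactly
## power-complementary (|H_LP|^2 + |H_HP|^2 = 1), so the bands sum back to
## the band-limited input to numerical precision. `order` is the one-pass
## Butterworth order (the effective zero-phase rolloff is twice that,
## Linkwitz-Riley style). Returns a list of sample vectors, one per band.
band_split_tree <- function(samples, edges_hz, fs, order = 4) {
  nyq <- fs / 2
  pre <- samples
  if (edges_hz[1] > 0) {
    pre <- signal::filtfilt(signal::butter(order, edges_hz[1] / nyq, "high"), pre)
  }
  top <- edges_hz[length(edges_hz)]
  if (top < 0.999 * nyq) {
    pre <- signal::filtfilt(signal::butter(order, top / nyq, "low"), pre)
  }
  n_bands <- length(edges_hz) - 1L
  bands <- vector("list", n_bands)
  rem <- pre
  for (b in seq_len(n_bands - 1L)) {
    w <- edges_hz[b + 1L] / nyq
    bands[[b]] <- signal::filtfilt(signal::butter(order, w, "low"), rem)
    rem <- signal::filtfilt(signal::butter(order, w, "high"), rem)
  }
  bands[[n_bands]] <- rem
  bands
}

#' Split a signal into the hearing-aid channels
#'
#' Zero-phase (forward-backward) Butterworth crossover filtering at the
#' channel-bank edges (see `band_split_tree` internals): adjacent channels
#' are power-complementary, so the channel signals sum back to the
#' band-limited input to within numerical precision.
#'
#' @param x A [calibrated_signal()] with sample rate of at least 16 kHz.
#' @param bank A [channel_bank()].
#' @param order One-pass Butterworth order of each crossover filter (the
#'   zero-phase application doubles the effective rolloff).
#' @return A list of 5 [calibrated_signal()] channel signals.
#' @export
filterbank_split <- function(x, bank = channel_bank(), order = 4) {
  stopifnot(inherits(x, "calibrated_signal"), inherits(bank, "channel_bank"))
  if (x$sample_rate_hz < 2 * bank$edges_hz[length(bank$edges_hz)]) {
    stop("undersampled for the channel bank", call. = FALSE)
  }
  lapply(band_split_tree(x$samples, bank$edges_hz, x$sample_rate_hz, order),
         function(s) calibrated_signal(s, x$sample_rate_hz, x$ref_db_spl))
}

#' Compressor parameters
#'
#' @param ct_db_spl Input-referred compression threshold in dB SPL.
#' @param cr Compression ratio (>= 1; 1 is linear).
#' @param gain_db Linear gain applied below the threshold.
#' @param attack_ms,release_ms Time constants of the level estimator for
#'   rising and falling levels.
#' @return An object of class `compressor_params`.
#' @export
compressor_params <- function(ct_db_spl, cr, gain_db = 0,
                              attack_ms = 100, release_ms = 1000) {
  if (cr < 1) stop("compression ratio must be >= 1", call. = FALSE)
  if (attack_ms <= 0 || release_ms <= 0) stop("time constants must be > 0", call. = FALSE)
  structure(list(ct_db_spl = ct_db_spl, cr = cr, gain_db = gain_db,
                 attack_ms = attack_ms, release_ms = release_ms),
            class = "compressor_params")
}

## Default output limiter: a second compressor in series after each
## channel's main compressor. Parameters are a conventional fast limiter.
limiter_params <- function(ct_db_spl = 100, cr = 10,
                           attack_ms = 5, release_ms = 50) {
  compressor_params(ct_db_spl, cr, 0, attack_ms, release_ms)
}

## Time-varying gain (dB) of a compressor given a smoothed input level
## trace (dB SPL): gain_db below CT, slope 1/CR above.
compressor_gain_db <- function(level_db, p) {
  p$gain_db - pmax(level_db - p$ct_db_spl, 0) * (1 - 1 / p$cr)
}

## Smoothed level trace (dB SPL) from instantaneous power: a short
## symmetric RMS pre-smoother (removes the within-period ripple that would
## otherwise bias the asymmetric stage toward the waveform peaks) followed
## by the attack/release follower. Column-wise over matrices.
detect_level_db <- function(power, fs, attack_ms, release_ms, ref_db_spl,
                            presmooth_ms = 5) {
  power <- as.matrix(power)
  a_sym <- smoothing_alpha(presmooth_ms, fs)
  env <- .env_follow(.env_follow(power, a_sym, a_sym),
                     smoothing_alpha(attack_ms, fs),
                     smoothing_alpha(release_ms, fs))
  10 * log10(pmax(env, 1e-30)) + ref_db_spl
}

#' Apply a dynamic-range compressor to a channel signal
#'
#' Feed-forward design: the input level is estimated as RMS (one-pole
#' smoothing of instantaneous power with separate attack and release time
#' constants), and the static input/output rule is `out = in + gain` below
#' the compression threshold and `out = ct + gain + (in - ct) / cr` above
#' it. `block > 1` computes the gain at a reduced control rate (one gain
#' value per block of samples), the usual trick for slow compressors.
#'
#' @param x A [calibrated_signal()] channel signal.
#' @param p A [compressor_params()].
#' @param block Control-block length in samples (default 1: per-sample gain).
#' @return The compressed [calibrated_signal()].
#' @export
compress_channel <- function(x, p, block = 1) {
  stopifnot(inherits(x, "calibrated_signal"), inherits(p, "compressor_params"))
  n <- length(x$samples)
  if (n == 0) return(x)
  fs_ctrl <- x$sample_rate_hz / block
  pw <- block_power(x$samples, block)
  lev <- detect_level_db(pw, fs_ctrl, p$attack_ms, p$release_ms, x$ref_db_spl)[, 1]
  g <- db_to_lin(compressor_gain_db(lev, p))
  x$samples <- x$samples * rep(g, each = block)[seq_len(n)]
  x
}

## Slow per-channel attack/release times (ms), channels 1-5.
CHANNEL_ATTACK_MS  <- c(200, 100, 100, 100, 100)
CHANNEL_RELEASE_MS <- c(2000, 1500, 1200, 1000, 1000)

## Per-channel static settings derived from a resolved prescription: CR from
## the two-level gains at the channel centre, and the below-threshold gain
## anchored so that the 65-dB SPL operating point receives IGSP65. The
## operating level per channel is measured on the input normalized to a
## 65-dB SPL broadband long-term level.
channel_static_settings <- function(resolved, ct_db_spl, bank, level65_ch) {
  idx <- match(bank$center_frequency_hz, resolved$frequencies_hz)
  ig65 <- resolved$ig_sp65[idx]
  ig85 <- resolved$ig_sp85[idx]
  cr <- clamp(compression_ratio(ig65, ig85), 1, bank$max_cr)
  gain <- ig65 + pmax(level65_ch - ct_db_spl, 0) * (1 - 1 / cr)
  list(ig65 = ig65, cr = cr, gain_db = gain)
}

#' Amplify a signal through the five-channel hearing aid
#'
#' Splits the input into the bank's channels and runs each through its main
#' dynamic-range compressor (compression threshold from the configuration,
#' compression ratio derived from the two-level insertion gains at the
#' channel centre, slow attack/release) followed by an output limiter, then
#' sums the channels. The below-threshold gain is anchored so a 65-dB SPL
#' speech input receives IGSP65 in each channel.
#'
#' @param x A [calibrated_signal()].
#' @param config An [ha_config()] (or a [prescription()], taken as-is with
#'   its own compression thresholds).
#' @param bank A [channel_bank()].
#' @param order Filterbank order, see [filterbank_split()].
#' @param block Control-block length for the compressors (samples).
#' @param limiter A [compressor_params()] for the output limiter, or `NULL`
#'   to disengage it.
#' @return The amplified [calibrated_signal()].
#' @export
amplify <- function(x, config, bank = channel_bank(), order = 4, block = 1,
                    limiter = limiter_params()) {
  stopifnot(inherits(x, "calibrated_signal"))
  if (inherits(config, "prescription")) {
    config <- ha_config(ct_db_spl = config$ct_db_spl, dig = rep(0, bank$n_channels),
                        resolved = config)
  }
  stopifnot(inherits(config, "ha_config"))
  if (any(config$ct_db_spl < 20 | config$ct_db_spl > 50)) {
    stop("constraint violation: compression thresholds outside [20, 50] dB SPL",
         call. = FALSE)
  }
  chans <- filterbank_split(x, bank, order)
  lev_in <- rms_level(x)
  lev_ch <- vapply(chans, rms_level, numeric(1))
  level65 <- lev_ch + (65 - lev_in)
  st <- channel_static_settings(config$resolved, config$ct_db_spl, bank, level65)
  out <- 0
  for (ch in seq_len(bank$n_channels)) {
    p <- compressor_params(config$ct_db_spl[ch], st$cr[ch], st$gain_db[ch],
                           CHANNEL_ATTACK_MS[ch], CHANNEL_RELEASE_MS[ch])
    y <- compress_channel(chans[[ch]], p, block)
    if (!is.null(limiter)) y <- compress_channel(y, limiter, block)
    out <- out + y$samples
  }
  calibrated_signal(out, x$sample_rate_hz, x$ref_db_spl)
}
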