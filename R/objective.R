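#' Intelligibility result
#'
#' The outcome of scoring a token set: the percent-correct score (in steps
#' of `100 / N` for `N` tokens) and a continuous likelihood used to break
#' ties between configurations with equal scores.
#'
#' @param score_percent Percent of tokens recognized, 0--100.
#' @param likelihood Continuous secondary score (higher is better).
#' @param per_token Optional data frame with per-token `metric` and
#'   `recognized` columns.
#' @return An object of class `intelligibility_result`.
#' @export
intelligibility_result <- function(score_percent, likelihood, per_token = NULL) {
  stopifnot(is.finite(likelihood))
  structure(list(score_percent = score_percent, likelihood = likelihood,
                 per_token = per_token),
            class = "intelligibility_result")
}

#' @export
print.intelligibility_result <- function(x, ...) {
  cat(sprintf("Intelligibility: %.1f%% (likelihood %.4f)\n",
              x$score_percent, x$likelihood))
  invisible(x)
}

## Score a vector of per-token metric values against a recognition
## threshold. The likelihood averages the metric over recognized tokens,
## falling back to all tokens when none are recognized (keeps the
## tie-breaker total).
score_from_metrics <- function(metrics, threshold = 0.5) {
  if (length(metrics) == 0) stop("no tokens to score", call. = FALSE)
  rec <- metrics >= threshold
  lik <- if (any(rec)) mean(metrics[rec]) else mean(metrics)
  intelligibility_result(
    100 * mean(rec), lik,
    per_token = data.frame(metric = metrics, recognized = rec)
  )
}

## Band frame envelopes (dB) of a signal: frame RMS level per channel,
## floored 50 dB below the frame maximum of the reference (floor_db).
band_frame_env <- function(x, bank, frame_ms = 16, order = 4) {
  frames <- max(1L, round(x$sample_rate_hz * frame_ms / 1000))
  chans <- filterbank_split(x, bank, order)
  sapply(chans, function(ch) {
    10 * log10(pmax(block_power(ch$samples, frames)[, 1], 1e-30)) + x$ref_db_spl
  })
}

## Clipped correlation between reference and processed frame sequences.
## Zero-variance reference frames are uninformative (NA, skipped by the
## caller's mean); a flat processed envelope against a varying reference
## scores 0.
clipped_cor <- function(ref, proc) {
  if (sd(ref) < 1e-9) return(NA_real_)
  if (sd(proc) < 1e-9) return(0)
  clamp(cor(ref, proc), 0, 1)
}

## Row-wise clipped correlations between two matrices (one correlation per
## row), vectorized; same degenerate-case conventions as clipped_cor.
rowwise_clipped_cor <- function(R, D) {
  Rc <- R - rowMeans(R)
  Dc <- D - rowMeans(D)
  vr <- rowSums(Rc^2)
  vd <- rowSums(Dc^2)
  r <- rowSums(Rc * Dc) / sqrt(pmax(vr * vd, 1e-30))
  r <- clamp(r, 0, 1)
  r[vd < 1e-9] <- 0
  r[vr < 1e-9] <- NA_real_
  r
}

## Combined envelope metric for one token from frame-by-band log-envelope
## matrices (frames x bands, dB): the mean of (i) per-band temporal
## correlations of the frame sequences and (ii) per-frame spectral
## correlations of the band profiles. The temporal part measures envelope
## preservation; the spectral part measures preservation of the speech
## spectrum's shape (per-frame correlation across bands is invariant to an
## overall dB shift but not to gains that tilt the spectrum), mirroring a
## recognizer's sensitivity to spectral shape rather than level.
env_cor_metric <- function(ref_mat, deg_mat) {
  temporal <- vapply(seq_len(ncol(ref_mat)), function(b) {
    clipped_cor(ref_mat[, b], deg_mat[, b])
  }, numeric(1))
  spectral <- rowwise_clipped_cor(ref_mat, deg_mat)
  parts <- c(mean(temporal, na.rm = TRUE), mean(spectral, na.rm = TRUE))
  parts[is.nan(parts)] <- NA
  if (all(is.na(parts))) 0 else mean(parts, na.rm = TRUE)
}

#' Envelope-correlation intelligibility metric for one token
#'
#' A short-time objective-intelligibility-style surrogate for a speech
#' recognizer: the processed token is level-aligned to the clean reference
#' (mirroring a recognizer's input normalization, which makes the metric
#' invariant to overall gain), both are decomposed into the channel bank's
#' bands, and the frame-by-band log-envelope matrices are compared by the
#' mean of per-band temporal correlations and per-frame spectral-profile
#' correlations, each clipped to \[0, 1\] (see the methods vignette). The
#' spectral component makes the metric sensitive to amplification that
#' tilts the speech spectrum while staying invariant to overall level. The
#' metric is 1 for an identical signal and near 0 for silence or an
#' unrelated envelope.
#'
#' @param processed,clean_reference [calibrated_signal()] objects at the
#'   same sample rate with the same token identity.
#' @param bank A [channel_bank()] defining the analysis bands.
#' @param frame_ms Envelope frame length in ms.
#' @param floor_rel_db Envelope floor relative to the reference maximum (dB).
#' @return Metric value in \[0, 1\].
#' @export
token_metric <- function(processed, clean_reference, bank = channel_bank(),
                         frame_ms = 16, floor_rel_db = 50) {
  stopifnot(inherits(processed, "calibrated_signal"),
            inherits(clean_reference, "calibrated_signal"))
  if (processed$sample_rate_hz != clean_reference$sample_rate_hz) {
    stop("sample rates differ", call. = FALSE)
  }
  n_p <- length(processed$samples)
  n_r <- length(clean_reference$samples)
  if (abs(n_p - n_r) > 0.1 * n_r) {
    stop("misaligned token: length mismatch beyond tolerance", call. = FALSE)
  }
  n <- min(n_p, n_r)
  processed$samples <- processed$samples[seq_len(n)]
  clean_reference$samples <- clean_reference$samples[seq_len(n)]
  if (is.finite(rms_level(processed))) {
    processed <- set_level(processed, rms_level(clean_reference))
  }
  ref_env <- band_frame_env(clean_reference, bank, frame_ms)
  proc_env <- band_frame_env(processed, bank, frame_ms)
  floor_db <- max(ref_env) - floor_rel_db
  env_cor_metric(pmax(ref_env, floor_db), pmax(proc_env, floor_db))
}

#' Score a set of processed tokens against clean references
#'
#' Each token is recognized when its [token_metric()] reaches `threshold`
#' (the stand-in for a recognizer's top-5 decision rule). The score is the
#' percentage of recognized tokens; the likelihood is the mean metric over
#' recognized tokens (over all tokens when none is recognized).
#'
#' @param processed,reference Lists of [calibrated_signal()] tokens, matched
#'   by position.
#' @param threshold Recognition threshold on the metric (default 0.5).
#' @param bank A [channel_bank()].
#' @param ... Passed to [token_metric()].
#' @return An [intelligibility_result()].
#' @export
score_tokens <- function(processed, reference, threshold = 0.5,
                         bank = channel_bank(), ...) {
  if (length(processed) == 0 || length(processed) != length(reference)) {
    stop("no tokens, or processed/reference sets of different size", call. = FALSE)
  }
  metrics <- vapply(seq_along(processed), function(i) {
    token_metric(processed[[i]], reference[[i]], bank = bank, ...)
  }, numeric(1))
  score_from_metrics(metrics, threshold)
}

## ---- parameter normalization shared by the quadratic objective ----------

## Parameters in units of their search stepsize (0.1 dB gains, 1 dB
## thresholds), so each coordinate contributes to distances at its own
## resolution.
normalize_params <- function(dig, ct) {
  c(dig / 0.1, ct / 1)
}

#' Deterministic quadratic test objective
#'
#' An optimizer oracle: the score is a quantized Gaussian bump around a
#' hidden optimum in normalized parameter space,
#' `floor_to_grid(100 * exp(-d^2 / tau))` with `d` the Euclidean distance to
#' the optimum of the parameters expressed in units of their search
#' stepsizes (0.1 dB for gain offsets, 1 dB for compression thresholds), and
#' the grid step `100 / n_tokens` (the granularity a token-counting score
#' would have). The likelihood is `-d`, so ties on the quantized score are
#' broken toward the closer configuration.
#'
#' @param dig,ct_db_spl Candidate per-channel gain offsets and compression
#'   thresholds.
#' @param optimum A list with elements `dig` and `ct_db_spl`: the hidden
#'   optimum.
#' @param tau Width of the score bump in squared normalized distance.
#' @param n_tokens Score granularity (default 50 tokens, i.e. 2% steps).
#' @return An [intelligibility_result()].
#' @export
quadratic_test_objective <- function(dig, ct_db_spl, optimum, tau = 1000,
                                     n_tokens = 50) {
  z <- normalize_params(dig, ct_db_spl)
  zo <- normalize_params(optimum$dig, optimum$ct_db_spl)
  if (length(z) != length(zo)) stop("parameter dimensions do not match", call. = FALSE)
  d <- sqrt(sum((z - zo)^2))
  step <- 100 / n_tokens
  intelligibility_result(floor(100 * exp(-d^2 / tau) / step) * step, -d)
}

#' Search objectives
#'
#' Constructors for the objective objects consumed by the search algorithms
#' ([gen1_run()] and friends). An objective is a list with an
#' `$evaluate(dig, ct_db_spl)` function returning an
#' [intelligibility_result()], plus bookkeeping fields.
#'
#' `make_quadratic_objective()` wraps [quadratic_test_objective()] (no audio
#' processing; used to validate optimizer behaviour against a known
#' optimum).
#'
#' @param optimum Hidden optimum, list with `dig` and `ct_db_spl`.
#' @param tau,n_tokens See [quadratic_test_objective()].
#' @return An object of class `rs_objective`.
#' @export
make_quadratic_objective <- function(optimum, tau = 1000, n_tokens = 50) {
  structure(
    list(evaluate = function(dig, ct_db_spl) {
           quadratic_test_objective(dig, ct_db_spl, optimum, tau, n_tokens)
         },
         label = "quadratic"),
    class = "rs_objective"
  )
}

#' Surrogate speech-intelligibility objective over the full processing chain
#'
#' Builds a fast objective that, for each candidate configuration, resolves
#' the constraints (compression-ratio rules and SII equalization against the
#' baseline prescription), amplifies the speech tokens through the
#' five-channel compressor + limiter chain, degrades them with the
#' loudness-recruitment loss simulator, and scores them with the
#' envelope-correlation metric against the clean tokens.
#'
#' For speed the per-candidate processing runs in the block-envelope domain:
#' the channel decomposition and the smoothed input-level traces of the
#' clean tokens are precomputed once (they do not depend on the candidate),
#' and compression, limiting and recruitment are applied to 1-ms block power
#' envelopes per channel. [amplify()] and [simulate_loss()] are the
#' waveform-domain reference implementations of the same stages.
#'
#' @param a A complete [audiogram()].
#' @param tokens A [generate_tokens()] token set (or a list of
#'   [calibrated_signal()] tokens).
#' @param bank A [channel_bank()].
#' @param rule Baseline prescription rule identifier.
#' @param threshold Recognition threshold on the token metric.
#' @param block_ms Control-block length in ms.
#' @param frame_ms Metric frame length in ms.
#' @param ceiling_db_spl Recruitment ceiling level.
#' @param limiter Output limiter parameters ([compressor_params()]).
#' @return An object of class `rs_objective` whose `evaluate(dig, ct_db_spl)`
#'   returns an [intelligibility_result()] with the resolved [ha_config()]
#'   attached as attribute `"config"`. The baseline prescription is exposed
#'   as `$baseline`.
#' @export
make_surrogate_objective <- function(a, tokens, bank = channel_bank(),
                                     rule = "linear6585", threshold = 0.5,
                                     block_ms = 1, frame_ms = 16,
                                     ceiling_db_spl = 100,
                                     limiter = limiter_params()) {
  stopifnot(inherits(a, "audiogram"))
  if (inherits(tokens, "token_set")) tokens <- tokens$tokens
  fs <- tokens[[1]]$sample_rate_hz
  ref_db <- tokens[[1]]$ref_db_spl
  block <- max(1L, round(fs * block_ms / 1000))
  frame_blocks <- max(1L, round(frame_ms / block_ms))
  n_tok <- length(tokens)
  lens <- vapply(tokens, function(t) length(t$samples), integer(1))
  n_max <- max(lens)
  X <- matrix(0, n_max, n_tok)
  for (i in seq_len(n_tok)) X[seq_len(lens[i]), i] <- tokens[[i]]$samples

  nch <- bank$n_channels
  splits <- apply(X, 2, function(col) {
    band_split_tree(col, bank$edges_hz, fs, 4)
  }, simplify = FALSE)
  blockp <- vector("list", nch)   # block power per channel (B x N)
  lin_db <- vector("list", nch)   # smoothed input level traces (dB SPL)
  fs_ctrl <- fs / block
  for (ch in seq_len(nch)) {
    xb <- vapply(splits, function(s) s[[ch]], numeric(n_max))
    bp <- block_power(xb, block)
    blockp[[ch]] <- bp
    lin_db[[ch]] <- detect_level_db(bp, fs_ctrl, CHANNEL_ATTACK_MS[ch],
                                    CHANNEL_RELEASE_MS[ch], ref_db)
  }
  n_blocks <- nrow(blockp[[1]])
  blk_valid <- pmin(ceiling(lens / block), n_blocks)
  n_frames_tok <- pmax(1L, floor(blk_valid / frame_blocks))

  frame_env_db <- function(pw_db) {
    ## aggregate block power (dB in, dB out) into metric frames
    pw <- 10^(pw_db / 10)
    fe <- block_power(sqrt(pw), frame_blocks)  # frame mean power
    10 * log10(pmax(fe, 1e-30))
  }
  ref_frames <- lapply(blockp, function(bp) {
    frame_env_db(10 * log10(pmax(bp, 1e-30)))
  })
  floor_db <- max(vapply(ref_frames, max, numeric(1))) + ref_db - 50 - ref_db

  ## long-term operating levels for the gain anchor (ensemble over tokens)
  tot_pw <- sum(X^2)
  lev_in <- 10 * log10(tot_pw / sum(lens)) + ref_db
  level65 <- vapply(blockp, function(bp) {
    10 * log10(sum(bp * block) / sum(lens)) + ref_db
  }, numeric(1)) + (65 - lev_in)

  hl <- pmax(interp_log2(a$frequencies_hz, a$thresholds_db_hl,
                         bank$center_frequency_hz), 0)
  if (any(hl >= ceiling_db_spl)) {
    stop("unsimulatable loss for the surrogate objective", call. = FALSE)
  }

  speech_spectrum <- spectrum_of_signal(
    calibrated_signal(as.numeric(X)[rep(seq_len(n_max), n_tok) <=
                                      rep(lens, each = n_max)], fs, ref_db)
  )
  baseline <- baseline_prescription(a, bank, rule)

  token_metrics <- function(deg_frames) {
    ## deg_frames / ref_frames: lists (per channel) of F x N dB matrices
    m <- numeric(n_tok)
    for (i in seq_len(n_tok)) {
      fr <- seq_len(n_frames_tok[i])
      R <- matrix(vapply(ref_frames, function(x) x[fr, i],
                         numeric(length(fr))), nrow = length(fr))
      D <- matrix(vapply(deg_frames, function(x) x[fr, i],
                         numeric(length(fr))), nrow = length(fr))
      m[i] <- env_cor_metric(pmax(R, floor_db), pmax(D, floor_db))
    }
    m
  }

  evaluate <- function(dig, ct_db_spl) {
    cfg <- resolve_config(dig, ct_db_spl, baseline, bank, a, speech_spectrum)
    st <- channel_static_settings(cfg$resolved, ct_db_spl, bank, level65)
    deg_frames <- vector("list", nch)
    for (ch in seq_len(nch)) {
      g_main <- compressor_gain_db(
        lin_db[[ch]],
        compressor_params(ct_db_spl[ch], st$cr[ch], st$gain_db[ch],
                          CHANNEL_ATTACK_MS[ch], CHANNEL_RELEASE_MS[ch])
      )
      out_pw <- blockp[[ch]] * 10^(g_main / 10)
      lim_lev <- detect_level_db(out_pw, fs_ctrl, limiter$attack_ms,
                                 limiter$release_ms, ref_db)
      out_pw <- out_pw * 10^(compressor_gain_db(lim_lev, limiter) / 10)
      out_lev <- 10 * log10(pmax(out_pw, 1e-30)) + ref_db
      deg_lev <- recruitment_map(out_lev, hl[ch], ceiling_db_spl)
      deg_frames[[ch]] <- frame_env_db(deg_lev - ref_db)
    }
    res <- score_from_metrics(token_metrics(deg_frames), threshold)
    attr(res, "config") <- cfg
    res
  }

  structure(
    list(evaluate = evaluate, label = "surrogate", baseline = baseline,
         audiogram = a, bank = bank, speech_spectrum = speech_spectrum),
    class = "rs_objective"
  )
}
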