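#' Loudness-recruitment level mapping
#'
#' Expansive dB-domain map modelling loudness recruitment: an input at the
#' elevated threshold `hl` maps to the normal threshold (0 dB SPL) and the
#' `ceiling` level maps to itself, i.e.
#' `mapped = (level - hl) * ceiling / (ceiling - hl)`. This equals raising
#' the signal envelope to the power `n = ceiling / (ceiling - hl)` (n = 1
#' for no loss; slope `n` >= 1 always, so the map is expansive and strictly
#' increasing).
#'
#' @param level_db_spl Input level(s) in dB SPL (vectorized).
#' @param hl Hearing loss in dB (>= 0, < `ceiling`).
#' @param ceiling_db_spl Level mapped to itself (default 100 dB SPL).
#' @return Mapped level(s) in dB SPL.
#' @export
#' @examples
#' recruitment_map(75, hl = 50)  # (75 - 50) * 2 = 50
recruitment_map <- function(level_db_spl, hl, ceiling_db_spl = 100) {
  if (any(hl >= ceiling_db_spl)) {
    stop("unsimulatable loss: hl must be below the ceiling level", call. = FALSE)
  }
  (level_db_spl - hl) * ceiling_db_spl / (ceiling_db_spl - hl)
}

## Audiometric octave bands used by the loss simulator (edges in Hz).
hl_band_edges <- function(fs) {
  edges <- c(89, 177, 354, 707, 1414, 2828, 5657, 8000)
  edges[edges <= fs / 2]
}

#' Simulate elevated thresholds and loudness recruitment
#'
#' Degrades a signal according to an audiogram: the signal is split into
#' audiometric octave bands, each band's RMS envelope (one-pole smoothing of
#' instantaneous power, 1-ms time constant) is mapped through
#' [recruitment_map()] with the band's hearing loss, and the fine structure
#' is preserved by applying the envelope gain multiplicatively before the
#' bands are recombined. The entire per-band loss is realized by the
#' recruitment expansion, which also enforces the threshold elevation; a
#' separate linear attenuation per band is available through
#' `attenuation_db` but defaults to zero. Loss of frequency selectivity is
#' deliberately not simulated.
#'
#' @param x A [calibrated_signal()].
#' @param a A complete [audiogram()]; negative thresholds are treated as
#'   zero loss.
#' @param ceiling_db_spl Level mapped to itself (default 100 dB SPL).
#' @param env_tau_ms Envelope smoothing time constant in ms.
#' @param attenuation_db Optional per-band linear attenuation (scalar or one
#'   value per band), applied before the expansion.
#' @param order Band filter order (see [filterbank_split()]).
#' @return The degraded [calibrated_signal()].
#' @export
simulate_loss <- function(x, a, ceiling_db_spl = 100, env_tau_ms = 1,
                          attenuation_db = 0, order = 4) {
  stopifnot(inherits(x, "calibrated_signal"), inherits(a, "audiogram"))
  if (!is_complete_audiogram(a)) {
    stop("complete audiogram required; see interpolate_missing_thresholds()",
         call. = FALSE)
  }
  edges <- hl_band_edges(x$sample_rate_hz)
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  hl <- pmax(interp_log2(a$frequencies_hz, a$thresholds_db_hl, centers), 0)
  if (any(hl >= ceiling_db_spl)) {
    stop("unsimulatable loss: band hearing loss at or above the ceiling level",
         call. = FALSE)
  }
  atten <- rep_len(attenuation_db, length(centers))
  bands <- band_split_tree(x$samples, edges, x$sample_rate_hz, order)
  alpha <- smoothing_alpha(env_tau_ms, x$sample_rate_hz)
  out <- 0
  for (b in seq_along(bands)) {
    xb <- bands[[b]]
    env_pw <- .env_follow(matrix(xb^2, ncol = 1), alpha, alpha)[, 1]
    lev <- 10 * log10(pmax(env_pw, 1e-30)) + x$ref_db_spl - atten[b]
    gain_db <- recruitment_map(lev, hl[b], ceiling_db_spl) - lev - atten[b]
    out <- out + xb * db_to_lin(gain_db)
  }
  calibrated_signal(out, x$sample_rate_hz, x$ref_db_spl)
}
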