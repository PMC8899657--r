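#' Compression ratio from the two-level insertion gains
#'
#' The compression ratio implied by the insertion gains at 65 and 85 dB SPL:
#' `CR = (85 - 65) / ((85 + ig85) - (65 + ig65)) = 20 / (20 + ig85 - ig65)`.
#' A zero denominator (output level independent of input level) returns the
#' `+Inf` sentinel.
#'
#' @param ig65,ig85 Insertion gains in dB for 65- and 85-dB SPL speech
#'   (vectorized).
#' @return The dimensionless compression ratio(s).
#' @export
#' @examples
#' compression_ratio(20, 2)   # 10, the simulator maximum
#' compression_ratio(15, 15)  # 1, linear
compression_ratio <- function(ig65, ig85) {
  den <- 20 + ig85 - ig65
  ifelse(den == 0, Inf, 20 / den)
}

#' Enforce the compression-ratio bounds on a gain pair
#'
#' Repeatedly applies the 0.5-dB adjustment rules until the compression
#' ratio lies in \[1, 10\]:
#' if CR < 0, IGSP85 is increased by 0.5 dB; if 0 <= CR < 1, IGSP65 is
#' increased by 0.5 dB; if CR > 10, IGSP65 is decreased by 0.5 dB. An
#' infinite CR (zero denominator) is handled by the CR > 10 rule. Inputs
#' already in range are returned unchanged.
#'
#' @param ig65,ig85 Insertion gains in dB (scalars).
#' @param max_cr Upper CR bound (default 10).
#' @return A list with elements `ig65`, `ig85`, `cr` and `steps` (number of
#'   0.5-dB adjustments applied).
#' @export
#' @examples
#' enforce_cr_bounds(0, 5)  # CR 0.8 -> ten steps up on ig65, CR becomes 1
enforce_cr_bounds <- function(ig65, ig85, max_cr = 10) {
  stopifnot(length(ig65) == 1L, length(ig85) == 1L,
            is.finite(ig65), is.finite(ig85))
  steps <- 0L
  repeat {
    cr <- compression_ratio(ig65, ig85)
    if (cr >= 1 && cr <= max_cr) break
    if (cr < 0) {
      ig85 <- ig85 + 0.5
    } else if (cr < 1) {
      ig65 <- ig65 + 0.5
    } else {
      ig65 <- ig65 - 0.5   # cr > max_cr, including the Inf sentinel
    }
    steps <- steps + 1L
  }
  list(ig65 = ig65, ig85 = ig85, cr = cr, steps = steps)
}

#' Hearing-aid configuration
#'
#' The searchable parameter set of the simulated hearing aid: one
#' compression threshold (CT) and one insertion-gain offset per channel,
#' plus the fully resolved prescription after offsets and all constraint
#' adjustments, and a provenance record of the adjustment steps applied.
#'
#' @param ct_db_spl Per-channel CT in dB SPL, within \[20, 50\].
#' @param dig Per-channel insertion-gain offset in dB relative to the
#'   baseline prescription, within \[-10, 10\].
#' @param resolved The resolved [prescription()].
#' @param provenance List of adjustment counts (see [resolve_config()]).
#' @return An object of class `ha_config`.
#' @export
ha_config <- function(ct_db_spl, dig, resolved, provenance = list()) {
  stopifnot(inherits(resolved, "prescription"))
  if (any(ct_db_spl < 20 | ct_db_spl > 50)) {
    stop("compression thresholds must lie within [20, 50] dB SPL", call. = FALSE)
  }
  if (any(dig < -10 | dig > 10)) {
    stop("gain offsets must lie within [-10, 10] dB", call. = FALSE)
  }
  structure(list(ct_db_spl = as.numeric(ct_db_spl), dig = as.numeric(dig),
                 resolved = resolved, provenance = provenance),
            class = "ha_config")
}

## Apply per-channel 65/85 gain corrections to all frequencies of each
## channel, keeping within-channel gains coherent.
apply_channel_corrections <- function(p, bank, d65, d85) {
  ch_of <- map_frequencies_to_channels(bank, p$frequencies_hz)
  p$ig_sp65 <- p$ig_sp65 + d65[ch_of]
  p$ig_sp85 <- p$ig_sp85 + d85[ch_of]
  p
}

## Run the per-channel CR rules at the channel centres and transport the
## corrections to every frequency of the channel. Returns the adjusted
## prescription and the number of 0.5-dB steps.
enforce_cr_bounds_prescription <- function(p, bank) {
  idx <- match(bank$center_frequency_hz, p$frequencies_hz)
  d65 <- d85 <- numeric(bank$n_channels)
  steps <- 0L
  for (ch in seq_len(bank$n_channels)) {
    adj <- enforce_cr_bounds(p$ig_sp65[idx[ch]], p$ig_sp85[idx[ch]], bank$max_cr)
    d65[ch] <- adj$ig65 - p$ig_sp65[idx[ch]]
    d85[ch] <- adj$ig85 - p$ig_sp85[idx[ch]]
    steps <- steps + adj$steps
  }
  list(prescription = apply_channel_corrections(p, bank, d65, d85), steps = steps)
}

#' Equalize candidate audibility to the baseline via 0.1-dB SII steps
#'
#' Shifts the candidate's insertion gains by a uniform offset, in 0.1-dB
#' quanta, until the absolute SII difference to the baseline prescription
#' can no longer be reduced. At each step the direction is the sign of
#' `SII_baseline - SII_candidate`; the first step that fails to reduce the
#' absolute difference is reverted and the loop stops. The shift is applied
#' to both IGSP65 and IGSP85 (preserving the per-channel compression
#' ratios).
#'
#' @param candidate,baseline [prescription()] objects.
#' @param a A complete [audiogram()].
#' @param speech_spectrum A [band_spectrum()] of the clean speech tokens;
#'   the SII is evaluated on these band levels raised by the insertion
#'   gains at the 65-dB SPL operating point.
#' @param step Offset quantum in dB (default 0.1).
#' @param max_steps Safety bound on the number of steps.
#' @return A list with the shifted `prescription`, the total `offset_db`
#'   applied, the number of `steps`, and `delta_final` (the remaining
#'   absolute SII difference).
#' @export
sii_equalize <- function(candidate, baseline, a, speech_spectrum,
                         step = 0.1, max_steps = 2000L) {
  sii_base <- sii_of_prescription(baseline, speech_spectrum, a)
  sii_at <- function(off) sii_of_prescription(candidate, speech_spectrum, a, off)
  if (!is.finite(sii_base)) stop("SII failure: non-finite baseline SII", call. = FALSE)
  offset <- 0
  cur <- sii_at(0)
  if (!is.finite(cur)) stop("SII failure: non-finite candidate SII", call. = FALSE)
  n_steps <- 0L
  while (n_steps < max_steps) {
    delta <- sii_base - cur
    if (delta == 0) break
    trial <- offset + sign(delta) * step
    trial_sii <- sii_at(trial)
    if (abs(sii_base - trial_sii) < abs(delta)) {
      offset <- trial
      cur <- trial_sii
      n_steps <- n_steps + 1L
    } else {
      break  # revert the non-improving step
    }
  }
  out <- candidate
  out$ig_sp65 <- out$ig_sp65 + offset
  out$ig_sp85 <- out$ig_sp85 + offset
  list(prescription = out, offset_db = offset, steps = n_steps,
       delta_final = abs(sii_base - cur))
}

#' Resolve a searched parameter set into a hearing-aid configuration
#'
#' The constraint pipeline applied to every candidate: (1) the per-channel
#' gain offsets are added to the baseline gains of all frequencies in the
#' channel (both input levels); (2) the compression-ratio rules are enforced
#' per channel at the channel centre; (3) if a speech spectrum is supplied,
#' the gains are SII-equalized to the baseline; (4) a final CR pass guards
#' the interaction of the uniform SII shift with the bounds. Resolved gains
#' are clamped to the representable \[-10, 80\] dB range.
#'
#' @param dig Per-channel gain offsets in dB.
#' @param ct_db_spl Per-channel compression thresholds in dB SPL.
#' @param baseline The baseline [prescription()].
#' @param bank A [channel_bank()].
#' @param a Audiogram for SII equalization (optional).
#' @param speech_spectrum Clean-speech [band_spectrum()] for SII
#'   equalization; `NULL` skips the equalization stage.
#' @return An [ha_config()] whose `provenance` records `cr_steps`,
#'   `sii_steps`, `sii_offset_db`, `sii_delta_final` and an `oob` flag (set
#'   when the SII shift pushed the effective offsets beyond the +/-10 dB
#'   search bounds).
#' @export
resolve_config <- function(dig, ct_db_spl, baseline, bank = channel_bank(),
                           a = NULL, speech_spectrum = NULL) {
  stopifnot(inherits(baseline, "prescription"))
  ch_of <- map_frequencies_to_channels(bank, baseline$frequencies_hz)
  p <- baseline
  p$ig_sp65 <- p$ig_sp65 + dig[ch_of]
  p$ig_sp85 <- p$ig_sp85 + dig[ch_of]
  enf <- enforce_cr_bounds_prescription(p, bank)
  p <- enf$prescription
  prov <- list(cr_steps = enf$steps, sii_steps = 0L, sii_offset_db = 0,
               sii_delta_final = NA_real_, oob = FALSE)
  if (!is.null(speech_spectrum)) {
    eq <- sii_equalize(p, baseline, a, speech_spectrum)
    p <- eq$prescription
    prov$sii_steps <- eq$steps
    prov$sii_offset_db <- eq$offset_db
    prov$sii_delta_final <- eq$delta_final
    prov$oob <- any(abs(dig + eq$offset_db) > 10)
    enf2 <- enforce_cr_bounds_prescription(p, bank)
    p <- enf2$prescription
    prov$cr_steps <- prov$cr_steps + enf2$steps
  }
  p$ig_sp65 <- clamp(p$ig_sp65, -10, 80)
  p$ig_sp85 <- clamp(p$ig_sp85, -10, 80)
  p$ct_db_spl <- as.numeric(ct_db_spl)
  ha_config(ct_db_spl, dig, p, prov)
}
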