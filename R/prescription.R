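#' Five-channel hearing-aid channel bank
#'
#' Defines the frequency channels of the simulated hearing aid: five
#' contiguous bands with edges 0.1, 0.7, 1.4, 2.8, 5.6 and 8 kHz by default,
#' and the maximum compression ratio the simulator allows (10).
#'
#' Each channel's centre frequency is the geometric mean of its edges,
#' snapped to the nearest of the 11 audiometric prescription frequencies.
#'
#' @param edges_hz Six strictly increasing band edges in Hz.
#' @param max_cr Maximum allowed compression ratio.
#' @return An object of class `channel_bank` with elements `edges_hz`,
#'   `center_frequency_hz` (length 5), `n_channels` and `max_cr`.
#' @export
#' @examples
#' channel_bank()$center_frequency_hz
channel_bank <- function(edges_hz = c(100, 700, 1400, 2800, 5600, 8000),
                         max_cr = 10) {
  edges_hz <- as.numeric(edges_hz)
  if (length(edges_hz) != 6L || any(diff(edges_hz) <= 0)) {
    stop("edges_hz must be 6 strictly increasing values (5 channels)", call. = FALSE)
  }
  n <- length(edges_hz) - 1L
  centers <- vapply(seq_len(n), function(ch) {
    snap_to_prescription_freq(sqrt(edges_hz[ch] * edges_hz[ch + 1L]))
  }, numeric(1))
  structure(
    list(edges_hz = edges_hz, center_frequency_hz = centers,
         n_channels = n, max_cr = max_cr),
    class = "channel_bank"
  )
}

snap_to_prescription_freq <- function(f) {
  AUDIOMETRIC_FREQS[which.min(abs(AUDIOMETRIC_FREQS - f))]
}

#' Channel centre frequency
#'
#' Geometric mean of a channel's edges snapped to the nearest of the 11
#' prescription frequencies. Degenerate channels (equal edges) return the
#' common edge.
#'
#' @param bank A [channel_bank()].
#' @param channel Channel index, 1--5.
#' @return Centre frequency in Hz.
#' @export
channel_center_frequency <- function(bank, channel) {
  stopifnot(inherits(bank, "channel_bank"))
  if (!channel %in% seq_len(bank$n_channels)) {
    stop("channel out of range", call. = FALSE)
  }
  lo <- bank$edges_hz[channel]
  hi <- bank$edges_hz[channel + 1L]
  if (lo == hi) return(lo)
  bank$center_frequency_hz[channel]
}

#' Assign prescription frequencies to channels
#'
#' Each of the audiometric frequencies is assigned to the channel whose
#' half-open interval \[lower edge, upper edge) contains it; the last
#' channel is closed above so the top frequency belongs to channel 5.
#'
#' @param bank A [channel_bank()].
#' @param frequencies_hz Frequencies to assign (default: the 11 prescription
#'   frequencies).
#' @return Integer vector of channel indices, one per frequency.
#' @export
#' @examples
#' table(map_frequencies_to_channels(channel_bank()))
map_frequencies_to_channels <- function(bank, frequencies_hz = AUDIOMETRIC_FREQS) {
  stopifnot(inherits(bank, "channel_bank"))
  idx <- findInterval(frequencies_hz, bank$edges_hz, rightmost.closed = TRUE)
  idx <- clamp(idx, 1L, bank$n_channels)
  as.integer(idx)
}

#' Construct a prescription
#'
#' A prescription holds the insertion gains recommended for speech input
#' levels of 65 and 85 dB SPL (IGSP65, IGSP85) at the 11 audiometric
#' frequencies, plus one compression threshold (CT, dB SPL) per channel.
#'
#' @param frequencies_hz The 11 prescription frequencies.
#' @param ig_sp65,ig_sp85 Insertion gains in dB at each frequency for 65-
#'   and 85-dB SPL speech. Must lie within \[-10, 80\] dB.
#' @param ct_db_spl Per-channel compression thresholds, within \[20, 50\]
#'   dB SPL.
#' @return An object of class `prescription`.
#' @export
prescription <- function(frequencies_hz = AUDIOMETRIC_FREQS,
                         ig_sp65, ig_sp85,
                         ct_db_spl = rep(35, 5)) {
  ig_sp65 <- as.numeric(ig_sp65)
  ig_sp85 <- as.numeric(ig_sp85)
  stopifnot(length(ig_sp65) == length(frequencies_hz),
            length(ig_sp85) == length(frequencies_hz))
  if (any(!is.finite(c(ig_sp65, ig_sp85))) ||
      any(c(ig_sp65, ig_sp85) < -10 | c(ig_sp65, ig_sp85) > 80)) {
    stop("insertion gains must be finite and within [-10, 80] dB", call. = FALSE)
  }
  if (any(ct_db_spl < 20 | ct_db_spl > 50)) {
    stop("compression thresholds must lie within [20, 50] dB SPL", call. = FALSE)
  }
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz),
         ig_sp65 = ig_sp65, ig_sp85 = ig_sp85,
         ct_db_spl = as.numeric(ct_db_spl)),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat("Prescription (IG dB at", length(x$frequencies_hz), "frequencies)\n")
  print(data.frame(frequency_hz = x$frequencies_hz,
                   ig_sp65 = round(x$ig_sp65, 2),
                   ig_sp85 = round(x$ig_sp85, 2)))
  cat("CT (dB SPL):", paste(round(x$ct_db_spl, 1), collapse = " "), "\n")
  invisible(x)
}

## ---- prescription-rule registry ------------------------------------------

.rule_registry <- new.env(parent = emptyenv())

#' Register a prescription rule
#'
#' A rule is a function `(thresholds_db_hl, frequencies_hz, ...)` returning a
#' list with numeric elements `ig_sp65` and `ig_sp85` (dB, one per
#' frequency). The built-in rules are:
#' \describe{
#'   \item{`"linear6585"`}{(default) IGSP65 = 0.45 HL, IGSP85 = 0.30 HL,
#'     floored at 0 and capped at 55 dB. A simple monotone, compressive
#'     stand-in for proprietary loudness-model rules: it guarantees
#'     IGSP85 <= IGSP65 so every downstream stage (compression-ratio
#'     computation, constraint enforcement, SII equalization) operates on
#'     realistic values.}
#'   \item{`"external"`}{echoes a user-supplied gain table (argument
#'     `table`: data frame with columns `frequency_hz`, `ig_sp65`,
#'     `ig_sp85`), so gains computed by any external fitting software can be
#'     plugged in.}
#' }
#'
#' @param name Rule identifier.
#' @param fn Rule function.
#' @export
register_prescription_rule <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .rule_registry)
  invisible(name)
}

#' Baseline prescription from an audiogram
#'
#' Applies a registered prescription rule to a complete audiogram to obtain
#' the baseline insertion-gain functions, and attaches the default
#' compression thresholds (35 dB SPL per channel, the midpoint of the
#' 20--50 dB SPL search range).
#'
#' @param a A complete [audiogram()] at the 11 prescription frequencies.
#' @param bank A [channel_bank()].
#' @param rule Rule identifier (see [register_prescription_rule()]).
#' @param ... Passed to the rule function (e.g. `table` for `"external"`).
#' @param ct_db_spl Per-channel compression thresholds.
#' @return A [prescription()].
#' @export
#' @examples
#' a <- audiogram(thresholds_db_hl = rep(40, 11))
#' baseline_prescription(a, channel_bank())
baseline_prescription <- function(a, bank = channel_bank(), rule = "linear6585",
                                  ..., ct_db_spl = rep(35, bank$n_channels)) {
  stopifnot(inherits(a, "audiogram"))
  if (!is_complete_audiogram(a)) {
    stop("audiogram must be complete; see interpolate_missing_thresholds()", call. = FALSE)
  }
  if (!exists(rule, envir = .rule_registry, inherits = FALSE)) {
    stop(sprintf("unregistered prescription rule '%s'", rule), call. = FALSE)
  }
  thr <- interp_log2(a$frequencies_hz, a$thresholds_db_hl, AUDIOMETRIC_FREQS)
  fn <- get(rule, envir = .rule_registry)
  g <- fn(thr, AUDIOMETRIC_FREQS, ...)
  prescription(AUDIOMETRIC_FREQS, g$ig_sp65, g$ig_sp85, ct_db_spl = ct_db_spl)
}

rule_linear6585 <- function(thresholds_db_hl, frequencies_hz, r65 = 0.45,
                            r85 = 0.30, cap_db = 55) {
  list(ig_sp65 = clamp(r65 * thresholds_db_hl, 0, cap_db),
       ig_sp85 = clamp(r85 * thresholds_db_hl, 0, cap_db))
}

rule_external <- function(thresholds_db_hl, frequencies_hz, table) {
  need <- c("frequency_hz", "ig_sp65", "ig_sp85")
  if (!all(need %in% names(table))) {
    stop("external rule table needs columns frequency_hz, ig_sp65, ig_sp85", call. = FALSE)
  }
  idx <- match(frequencies_hz, table$frequency_hz)
  if (anyNA(idx)) stop("external rule table missing prescription frequencies", call. = FALSE)
  list(ig_sp65 = as.numeric(table$ig_sp65[idx]),
       ig_sp85 = as.numeric(table$ig_sp85[idx]))
}

## Populate the registry at load time.
register_prescription_rule("linear6585", rule_linear6585)
register_prescription_rule("external", rule_external)

#' Read / write a prescription as JSON
#'
#' @param path File path.
#' @return `read_prescription()` returns a [prescription()];
#'   `write_prescription()` returns `path` invisibly.
#' @export
read_prescription <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  prescription(d$frequencies_hz, d$ig_sp65, d$ig_sp85, ct_db_spl = d$ct_db_spl)
}

#' @rdname read_prescription
#' @param p A [prescription()].
#' @export
write_prescription <- function(p, path) {
  stopifnot(inherits(p, "prescription"))
  jsonlite::write_json(unclass(p), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
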