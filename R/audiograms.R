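#' Construct an audiogram
#'
#' An audiogram stores pure-tone hearing thresholds (dB HL) at a set of
#' audiometric frequencies. Thresholds may be missing (`NA`) at some
#' frequencies; see [interpolate_missing_thresholds()] to complete them.
#'
#' @param frequencies_hz Strictly increasing positive frequencies in Hz.
#'   Defaults to the 11 standard audiometric frequencies 125--8000 Hz.
#' @param thresholds_db_hl Hearing levels in dB HL, one per frequency.
#'   Present values must lie in \[-10, 120\] dB HL; `NA` marks a missing
#'   measurement.
#' @param label Free-text identifier.
#'
#' @return An object of class `audiogram`: a list with elements
#'   `frequencies_hz`, `thresholds_db_hl` and `label`.
#' @export
#' @examples
#' a <- audiogram(thresholds_db_hl = c(NA, 20, 30, NA, 40, NA, 55, 60, 70, NA, 80))
#' pta(interpolate_missing_thresholds(a))
audiogram <- function(frequencies_hz = AUDIOMETRIC_FREQS,
                      thresholds_db_hl,
                      label = "") {
  frequencies_hz <- as.numeric(frequencies_hz)
  thresholds_db_hl <- as.numeric(thresholds_db_hl)
  if (length(frequencies_hz) != length(thresholds_db_hl)) {
    stop("frequencies_hz and thresholds_db_hl must have the same length", call. = FALSE)
  }
  if (any(frequencies_hz <= 0) || any(diff(frequencies_hz) <= 0)) {
    stop("frequencies must be positive and strictly increasing", call. = FALSE)
  }
  present <- !is.na(thresholds_db_hl)
  if (any(!is.finite(thresholds_db_hl[present])) ||
      any(thresholds_db_hl[present] < -10 | thresholds_db_hl[present] > 120)) {
    stop("present thresholds must be finite and within [-10, 120] dB HL", call. = FALSE)
  }
  structure(
    list(frequencies_hz = frequencies_hz,
         thresholds_db_hl = thresholds_db_hl,
         label = as.character(label)[1]),
    class = "audiogram"
  )
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram", if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  print(setNames(x$thresholds_db_hl, paste0(x$frequencies_hz, "Hz")))
  invisible(x)
}

is_complete_audiogram <- function(a) !anyNA(a$thresholds_db_hl)

#' Fill in missing audiogram thresholds
#'
#' Missing thresholds are intra- or extrapolated with a third-order
#' least-squares polynomial fitted to the present (log2 frequency, threshold)
#' pairs. Present values are left untouched; filled values are clamped to
#' the audiometric range \[-10, 120\] dB HL.
#'
#' The fit uses log2 frequency as abscissa, the conventional audiometric
#' axis: a cubic in linear Hz extrapolates badly at the low frequencies.
#'
#' @param a An [audiogram()].
#' @return A complete `audiogram`.
#' @export
interpolate_missing_thresholds <- function(a) {
  stopifnot(inherits(a, "audiogram"))
  present <- !is.na(a$thresholds_db_hl)
  if (all(present)) return(a)
  if (sum(present) < 4L) {
    stop("under-determined fit: at least 4 present thresholds are required", call. = FALSE)
  }
  x <- log2(a$frequencies_hz[present])
  y <- a$thresholds_db_hl[present]
  fit <- lm(y ~ poly(x, degree = 3, raw = TRUE))
  x_new <- log2(a$frequencies_hz[!present])
  pred <- cbind(1, x_new, x_new^2, x_new^3) %*% coef(fit)
  a$thresholds_db_hl[!present] <- clamp(as.numeric(pred), -10, 120)
  a
}

#' Pure-tone average
#'
#' Arithmetic mean of the thresholds at 0.5, 0.75, 1, 1.5, 2, 3 and 4 kHz,
#' a scalar index of hearing-loss severity.
#'
#' @param a An [audiogram()] with thresholds present at all 7 PTA frequencies.
#' @return The PTA in dB HL.
#' @export
pta <- function(a) {
  stopifnot(inherits(a, "audiogram"))
  idx <- match(PTA_FREQS, a$frequencies_hz)
  if (anyNA(idx) || anyNA(a$thresholds_db_hl[idx])) {
    stop("incomplete audiogram: thresholds required at 500-4000 Hz PTA frequencies",
         call. = FALSE)
  }
  mean(a$thresholds_db_hl[idx])
}

## Base sloping-loss profiles (dB HL at the 11 audiometric frequencies) for
## severity levels 4-7 of an age-related hearing-loss classification: mild
## through moderately-severe high-frequency sloping losses, monotonically
## non-decreasing with frequency, PTA strictly increasing with level.
SEVERITY_PROFILES <- rbind(
  `4` = c(10, 10, 10, 15, 15, 20, 25, 35, 45, 55, 60),
  `5` = c(15, 15, 15, 20, 25, 30, 40, 50, 55, 65, 70),
  `6` = c(20, 20, 25, 30, 35, 45, 55, 60, 65, 75, 80),
  `7` = c(30, 30, 35, 40, 50, 60, 65, 70, 80, 85, 90)
)

#' Synthesize a sloping-loss audiogram
#'
#' Generates deterministic, seeded audiograms emulating age-related
#' high-frequency sloping hearing losses at four severity levels. With
#' `jitter = 0` the output is the level's smooth mean profile shifted by a
#' small seeded offset (a "mean audiogram"); positive `jitter` adds
#' per-frequency noise, producing the more erratic shape of individual
#' audiograms.
#'
#' @param severity Integer severity level, 4 (mild) to 7 (moderately severe).
#' @param seed Integer seed; the same seed always yields the same audiogram.
#' @param jitter Standard deviation (dB) of per-frequency threshold noise.
#' @return An [audiogram()]; thresholds are rounded to 5 dB (audiometric
#'   convention) and clamped to \[-10, 120\] dB HL.
#' @export
#' @examples
#' synth_audiogram(6, seed = 7)
synth_audiogram <- function(severity, seed, jitter = 0) {
  if (!severity %in% 4:7) {
    stop("invalid severity level: must be one of 4, 5, 6, 7", call. = FALSE)
  }
  stopifnot(jitter >= 0)
  base <- SEVERITY_PROFILES[as.character(severity), ]
  thr <- with_local_seed(seed, {
    shift <- rnorm(1, 0, 2.5)
    base + shift + rnorm(length(base), 0, jitter)
  })
  thr <- clamp(round_to_step(thr, 5), -10, 120)
  audiogram(AUDIOMETRIC_FREQS, thr,
            label = sprintf("synthetic-L%d-seed%d", severity, as.integer(seed)))
}

#' Read / write an audiogram CSV
#'
#' The CSV has two columns, `frequency_hz` and `threshold_db_hl` (header
#' required); a missing threshold is encoded as an empty field.
#'
#' @param path File path.
#' @param label Label for the audiogram read (defaults to the file name).
#' @return `read_audiogram()` returns an [audiogram()];
#'   `write_audiogram()` returns `path` invisibly.
#' @export
read_audiogram <- function(path, label = basename(path)) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frequency_hz", "threshold_db_hl") %in% names(d))) {
    stop("audiogram CSV must have columns frequency_hz, threshold_db_hl", call. = FALSE)
  }
  audiogram(d$frequency_hz, as.numeric(d$threshold_db_hl), label = label)
}

#' @rdname read_audiogram
#' @param a An [audiogram()] to write.
#' @export
write_audiogram <- function(a, path) {
  stopifnot(inherits(a, "audiogram"))
  write.csv(
    data.frame(frequency_hz = a$frequencies_hz, threshold_db_hl = a$thresholds_db_hl),
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}
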