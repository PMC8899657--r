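## Fixtures and orchestration: synthetic speech-like tokens, batch fitting
## runs, and reproducibility analysis across repetitions.

## Second-order resonator (formant) filter coefficients.
resonator <- function(f_hz, bw_hz, fs) {
  r <- exp(-pi * bw_hz / fs)
  theta <- 2 * pi * f_hz / fs
  list(b = 1 - r, a = c(1, -2 * r * cos(theta), r^2))
}

## One synthetic disyllabic token: a glottal-like sawtooth source with a
## declining f0, two "syllables" with their own random formant sets, a
## fricative-like noise burst at the second-syllable onset, and raised
## cosine amplitude envelopes.
synth_token <- function(fs) {
  dur <- runif(1, 0.4, 0.8)
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  f0 <- runif(1, 100, 140) * (1 - 0.15 * t / dur)
  phase <- cumsum(f0) / fs
  src <- 2 * (phase %% 1) - 1
  split <- round(n * runif(1, 0.35, 0.5))
  out <- numeric(n)
  for (syl in 1:2) {
    idx <- if (syl == 1) seq_len(split) else (split + 1L):n
    formants <- c(runif(1, 300, 800), runif(1, 900, 2200), runif(1, 2300, 3400))
    bws <- c(90, 140, 220)
    seg <- src[idx]
    for (k in 1:3) {
      rf <- resonator(formants[k], bws[k], fs)
      seg <- as.numeric(signal::filter(rf$b, rf$a, seg))
    }
    m <- length(idx)
    ramp <- round(0.04 * fs)
    env <- rep(1, m)
    up <- seq_len(min(ramp, m))
    env[up] <- 0.5 - 0.5 * cos(pi * up / length(up))
    env[m + 1 - up] <- pmin(env[m + 1 - up], 0.5 - 0.5 * cos(pi * up / length(up)))
    out[idx] <- seg * env / max(abs(seg) + 1e-12)
  }
  burst_len <- round(0.02 * fs)
  burst_at <- split + seq_len(min(burst_len, n - split))
  out[burst_at] <- out[burst_at] + 0.3 * runif(length(burst_at), -1, 1)
  out
}

#' Generate a set of distinct speech-like tokens
#'
#' Deterministic, seeded synthesis of speech-like test items (harmonic
#' source, per-token formant trajectories, a noise burst, 0.4--0.8 s) used
#' in place of recorded word lists: the intelligibility objective only
#' needs matched clean/processed pairs of mutually distinct tokens. Each
#' token is calibrated to a 65-dB SPL long-term level.
#'
#' @param n Number of tokens (default 50).
#' @param seed Integer seed; the same seed reproduces the same waveforms.
#' @param sample_rate Sample rate in Hz (>= 16 kHz).
#' @param level_db_spl Long-term RMS level per token.
#' @param ref_db_spl Calibration reference (dB SPL of unit RMS).
#' @return An object of class `token_set`: list with `tokens` (list of
#'   [calibrated_signal()]), `ids`, `sample_rate` and `seed`.
#' @export
generate_tokens <- function(n = 50, seed = 1, sample_rate = 16000,
                            level_db_spl = 65, ref_db_spl = 100) {
  stopifnot(n >= 1)
  tokens <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      set_level(calibrated_signal(synth_token(sample_rate), sample_rate,
                                  ref_db_spl),
                level_db_spl)
    })
  })
  structure(list(tokens = tokens, ids = sprintf("tok%03d", seq_len(n)),
                 sample_rate = sample_rate, seed = seed),
            class = "token_set")
}

run_algorithm <- function(algorithm, objective, budget, threads, seed, init) {
  switch(algorithm,
    gen1 = gen1_run(objective, budget, threads, seed, init),
    gen2 = gen2_run(objective, budget, threads, seed, init),
    gen3 = gen3_run(objective, ct_budget = budget %/% 3,
                    ig_budget = budget - budget %/% 3,
                    threads = threads, seed = seed, init = init),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Run a fitting experiment over a batch of audiograms
#'
#' For each audiogram and repetition, builds the surrogate objective,
#' evaluates the baseline prescription, runs the chosen search algorithm,
#' and collects the optimized settings. Per-audiogram failures are recorded
#' and the batch continues. Fully deterministic for a fixed `seed`.
#'
#' By default the baseline configuration (zero gain offsets, 35-dB SPL
#' thresholds) seeds the search (`init` of [gen1_run()] and friends), so the
#' rollback guarantee makes every optimized score at least the baseline
#' score.
#'
#' @param audiograms List of complete [audiogram()] objects.
#' @param algorithm `"gen1"`, `"gen2"` or `"gen3"`.
#' @param repetitions Number of independent repetitions per audiogram.
#' @param budget Search iterations per repetition.
#' @param threads Search threads.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param tokens A [generate_tokens()] token set (generated from `seed` when
#'   omitted).
#' @param include_baseline Seed the search with the baseline configuration.
#' @param out_dir Optional directory: writes `summary.csv`, per-run
#'   `settings_<audiogram>_rep<k>.json` and `runlog_<audiogram>_rep<k>.csv`.
#' @param ... Passed to [make_surrogate_objective()].
#' @return An object of class `experiment_result`: `summary` data frame
#'   (audiogram, repetition, baseline and optimized score/likelihood,
#'   error), and `runs[[audiogram_label]][[repetition]]` holding each
#'   `search_state` and resolved [prescription()].
#' @export
run_experiment <- function(audiograms, algorithm = "gen1", repetitions = 2,
                           budget = 75, threads = 4, seed = 1, tokens = NULL,
                           include_baseline = TRUE, out_dir = NULL, ...) {
  stopifnot(length(audiograms) >= 1)
  if (is.null(tokens)) tokens <- generate_tokens(50, seed)
  labels <- vapply(seq_along(audiograms), function(i) {
    l <- audiograms[[i]]$label
    if (nzchar(l)) l else sprintf("audiogram%02d", i)
  }, character(1))
  run_seeds <- with_local_seed(seed,
    matrix(sample.int(2^30, length(audiograms) * repetitions),
           nrow = length(audiograms)))
  rows <- list()
  runs <- setNames(vector("list", length(audiograms)), labels)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(audiograms)) {
    a <- audiograms[[i]]
    runs[[i]] <- vector("list", repetitions)
    for (r in seq_len(repetitions)) {
      row <- data.frame(audiogram = labels[i], repetition = r,
                        baseline_score = NA_real_, optimized_score = NA_real_,
                        optimized_likelihood = NA_real_, error = NA_character_)
      res <- tryCatch({
        obj <- make_surrogate_objective(a, tokens, ...)
        init <- if (include_baseline) list(dig = rep(0, 5), ct_db_spl = rep(35, 5))
        base_res <- obj$evaluate(rep(0, 5), rep(35, 5))
        state <- run_algorithm(algorithm, obj, budget, threads,
                               run_seeds[i, r], init)
        list(state = state, base = base_res,
             resolved = attr(state$best_result, "config")$resolved)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$baseline_score <- result_score(res$base)
        row$optimized_score <- result_score(res$state$best_result)
        row$optimized_likelihood <- result_lik(res$state$best_result)
        runs[[i]][[r]] <- res
        if (!is.null(out_dir)) {
          stem <- sprintf("%s_rep%d", gsub("[^A-Za-z0-9_-]", "_", labels[i]), r)
          write_prescription(res$resolved,
                             file.path(out_dir, paste0("settings_", stem, ".json")))
          log_df <- cbind(repetition = r, res$state$trace)
          write.csv(log_df, file.path(out_dir, paste0("runlog_", stem, ".csv")),
                    row.names = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  structure(list(summary = summary, runs = runs, algorithm = algorithm,
                 seed = seed),
            class = "experiment_result")
}

## Pull the resolved prescriptions of one repetition out of an experiment.
repetition_settings <- function(result, repetition) {
  stopifnot(inherits(result, "experiment_result"))
  lapply(result$runs, function(rr) rr[[repetition]]$resolved)
}

#' Compare the settings found by two repetitions
#'
#' For each audiogram, the Pearson correlation between the two repetitions'
#' 11-point IGSP65 functions, and the per-channel absolute difference in
#' compression thresholds.
#'
#' @param settings_rep1,settings_rep2 Named lists of resolved
#'   [prescription()] objects (matched by name), or a single
#'   `experiment_result` passed as `settings_rep1` (its repetitions 1 and 2
#'   are compared).
#' @return A list with `per_audiogram` (data frame of correlations),
#'   `delta_ct` (audiogram x channel matrix of absolute CT differences) and
#'   `summary` (min/max/mean correlation).
#' @export
compare_repetitions <- function(settings_rep1, settings_rep2 = NULL) {
  if (inherits(settings_rep1, "experiment_result")) {
    res <- settings_rep1
    settings_rep1 <- repetition_settings(res, 1)
    settings_rep2 <- repetition_settings(res, 2)
  }
  if (length(settings_rep1) != length(settings_rep2) ||
      !identical(names(settings_rep1), names(settings_rep2))) {
    stop("pairing error: repetition sets do not match", call. = FALSE)
  }
  keep <- !vapply(settings_rep1, is.null, logical(1)) &
    !vapply(settings_rep2, is.null, logical(1))
  settings_rep1 <- settings_rep1[keep]
  settings_rep2 <- settings_rep2[keep]
  r <- vapply(seq_along(settings_rep1), function(i) {
    cor(settings_rep1[[i]]$ig_sp65, settings_rep2[[i]]$ig_sp65)
  }, numeric(1))
  delta_ct <- t(vapply(seq_along(settings_rep1), function(i) {
    abs(settings_rep1[[i]]$ct_db_spl - settings_rep2[[i]]$ct_db_spl)
  }, numeric(5)))
  rownames(delta_ct) <- names(settings_rep1)
  list(per_audiogram = data.frame(audiogram = names(settings_rep1), r = r),
       delta_ct = delta_ct,
       summary = c(r_min = min(r), r_max = max(r), r_mean = mean(r)))
}
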