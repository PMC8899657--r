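#' Score tokens with an external speech recognizer
#'
#' Adapter contract for plugging a real recognizer into the fitting chain in
#' place of the surrogate metric. The processed tokens are written as WAV
#' files together with a manifest CSV (`token_id`, `target_word`,
#' `wav_path`); the user-supplied command is invoked with the manifest path
#' as its argument and must write `result.csv` (columns `token_id`,
#' `recognized` as 0/1, `log_likelihood`) next to the manifest. The score is
#' the percentage of recognized tokens and the likelihood is the mean
#' log-likelihood over recognized tokens (over all tokens when none is
#' recognized).
#'
#' @param processed List of [calibrated_signal()] tokens.
#' @param token_ids Character identifiers, one per token.
#' @param target_words Target word per token (written to the manifest).
#' @param command Command to invoke (passed to [system2()]).
#' @param args Extra arguments placed before the manifest path.
#' @param workdir Directory for the WAV files, manifest and result.
#' @param timeout Seconds before the command is aborted.
#' @return An [intelligibility_result()].
#' @export
external_asr_score <- function(processed, token_ids, target_words, command,
                               args = character(), workdir = tempfile("asr"),
                               timeout = 300) {
  stopifnot(length(processed) >= 1,
            length(token_ids) == length(processed),
            length(target_words) == length(processed))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  wavs <- file.path(workdir, paste0("token_", token_ids, ".wav"))
  for (i in seq_along(processed)) write_wav(processed[[i]], wavs[i])
  manifest <- file.path(workdir, "manifest.csv")
  write.csv(data.frame(token_id = token_ids, target_word = target_words,
                       wav_path = wavs),
            manifest, row.names = FALSE)
  status <- system2(command, c(args, manifest), stdout = FALSE, stderr = FALSE,
                    timeout = timeout)
  if (!identical(status, 0L)) {
    stop(sprintf("external recognizer failed (exit status %s)", status), call. = FALSE)
  }
  result_path <- file.path(workdir, "result.csv")
  if (!file.exists(result_path)) {
    stop("external recognizer did not write result.csv", call. = FALSE)
  }
  res <- read.csv(result_path)
  idx <- match(token_ids, as.character(res$token_id))
  if (anyNA(idx)) stop("result.csv does not cover all tokens", call. = FALSE)
  rec <- as.logical(res$recognized[idx])
  ll <- as.numeric(res$log_likelihood[idx])
  lik <- if (any(rec)) mean(ll[rec]) else mean(ll)
  intelligibility_result(100 * mean(rec), lik,
                         per_token = data.frame(metric = ll, recognized = rec))
}

#' Search objective backed by an external recognizer
#'
#' Resolves each candidate configuration, amplifies and degrades the tokens
#' with the waveform-domain simulators, and scores them through
#' [external_asr_score()]. This is the slow, recognizer-in-the-loop path;
#' see [make_surrogate_objective()] for the self-contained surrogate.
#'
#' @inheritParams make_surrogate_objective
#' @param target_words Target word per token.
#' @inheritParams external_asr_score
#' @param block Control-block length in samples for the simulators.
#' @return An object of class `rs_objective`.
#' @export
make_external_asr_objective <- function(a, tokens, command, target_words,
                                        args = character(),
                                        bank = channel_bank(),
                                        rule = "linear6585",
                                        workdir = tempfile("asr"),
                                        timeout = 300, block = 16) {
  if (inherits(tokens, "token_set")) {
    if (missing(target_words)) target_words <- tokens$ids
    tokens <- tokens$tokens
  }
  baseline <- baseline_prescription(a, bank, rule)
  cat_tokens <- calibrated_signal(
    unlist(lapply(tokens, function(t) t$samples)),
    tokens[[1]]$sample_rate_hz, tokens[[1]]$ref_db_spl
  )
  speech_spectrum <- spectrum_of_signal(cat_tokens)
  ids <- sprintf("%03d", seq_along(tokens))
  evaluate <- function(dig, ct_db_spl) {
    cfg <- resolve_config(dig, ct_db_spl, baseline, bank, a, speech_spectrum)
    proc <- lapply(tokens, function(t) {
      simulate_loss(amplify(t, cfg, bank, block = block), a)
    })
    res <- external_asr_score(proc, ids, target_words, command, args,
                              file.path(workdir, format(Sys.time(), "%H%M%OS3")),
                              timeout)
    attr(res, "config") <- cfg
    res
  }
  structure(list(evaluate = evaluate, label = "external-asr",
                 baseline = baseline, audiogram = a, bank = bank),
            class = "rs_objective")
}
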