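test_that("the token metric is 1 for identity, near 0 for silence, level-robust", {
  toks <- small_tokens()
  x <- toks$tokens[[1]]
  expect_equal(token_metric(x, x), 1)
  silence <- calibrated_signal(numeric(length(x$samples)), x$sample_rate_hz)
  expect_lte(token_metric(silence, x), 0.1)
  ## gain invariance within +/-12 dB (recognizer-style input normalization)
  for (g in c(-12, -6, 6, 12)) {
    att <- x
    att$samples <- att$samples * 10^(g / 20)
    expect_gte(token_metric(att, x), 0.95)
  }
  ## mismatched lengths beyond tolerance are refused
  short <- calibrated_signal(x$samples[1:1000], x$sample_rate_hz)
  expect_error(token_metric(short, x), "misaligned")
})

test_that("different tokens score below a token's self-similarity", {
  toks <- small_tokens()
  n <- min(4, length(toks$tokens))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      len_ok <- abs(length(toks$tokens[[j]]$samples) -
                      length(toks$tokens[[i]]$samples)) <=
        0.1 * length(toks$tokens[[i]]$samples)
      if (!len_ok) next
      expect_lt(token_metric(toks$tokens[[j]], toks$tokens[[i]]), 1)
    }
  }
})

test_that("token scoring counts recognitions and averages the tie-breaker", {
  toks <- small_tokens()
  refs <- toks$tokens[1:5]
  proc <- refs
  proc[[3]] <- calibrated_signal(numeric(length(refs[[3]]$samples)), FS)
  res <- score_tokens(proc, refs)
  expect_equal(res$score_percent, 80)  # 4 of 5 recognized
  expect_equal(res$likelihood, 1)      # mean metric over recognized tokens
  expect_equal(sum(res$per_token$recognized), 4)
  ## permutation invariance
  perm <- c(4, 2, 5, 1, 3)
  res_p <- score_tokens(proc[perm], refs[perm])
  expect_equal(res_p$score_percent, res$score_percent)
  expect_equal(res_p$likelihood, res$likelihood)
  ## all below threshold: score 0, likelihood falls back to the overall mean
  silent <- lapply(refs, function(r)
    calibrated_signal(numeric(length(r$samples)), FS))
  res0 <- score_tokens(silent, refs)
  expect_equal(res0$score_percent, 0)
  expect_equal(res0$likelihood, mean(res0$per_token$metric))
  expect_error(score_tokens(list(), list()), "no tokens")
})

test_that("the quadratic oracle quantizes its score and breaks ties by distance", {
  opt <- list(dig = rep(0, 5), ct_db_spl = rep(35, 5))
  at_opt <- quadratic_test_objective(opt$dig, opt$ct_db_spl, opt)
  expect_equal(at_opt$score_percent, 100)
  expect_equal(at_opt$likelihood, 0)
  ## d chosen so the raw score is 89: the 2%-floor quantization yields 88
  tau <- 1000
  d89 <- sqrt(-tau * log(0.89))
  r <- quadratic_test_objective(c(d89 * 0.1, 0, 0, 0, 0), opt$ct_db_spl, opt,
                                tau = tau)
  expect_equal(r$score_percent, 88)
  ## equal quantized scores, different distances: likelihood prefers closer
  r_near <- quadratic_test_objective(c(0.2, 0, 0, 0, 0), opt$ct_db_spl, opt)
  r_far <- quadratic_test_objective(c(0.4, 0, 0, 0, 0), opt$ct_db_spl, opt)
  expect_equal(r_near$score_percent, r_far$score_percent)
  expect_true(accept_candidate(r_far, r_near))
  expect_false(accept_candidate(r_near, r_far))
})

test_that("baseline amplification does not hurt the surrogate score under flat loss", {
  a <- flat_audiogram(40)
  toks <- small_tokens()
  refs <- toks$tokens[1:4]
  b <- channel_bank()
  p <- baseline_prescription(a, b)
  amplified <- lapply(refs, function(x) simulate_loss(amplify(x, p, b, block = 16), a))
  unaided <- lapply(refs, function(x) simulate_loss(x, a))
  res_amp <- score_tokens(amplified, refs)
  res_un <- score_tokens(unaided, refs)
  expect_gte(res_amp$score_percent, res_un$score_percent)
})

test_that("the envelope-domain objective matches the waveform chain on levels", {
  a <- synth_audiogram(5, seed = 3)
  toks <- small_tokens()
  b <- channel_bank()
  obj <- make_surrogate_objective(a, toks)
  res <- obj$evaluate(rep(0, 5), rep(35, 5))
  cfg <- attr(res, "config")
  expect_s3_class(cfg, "ha_config")
  ## waveform reference path on one token
  x <- toks$tokens[[1]]
  y <- simulate_loss(amplify(x, cfg, b, block = 16), a,
                     ceiling_db_spl = 100)
  expect_true(is.finite(rms_level(y)))
  ## both paths agree that amplification raised the presentation level
  expect_gt(rms_level(y), rms_level(x))
  expect_true(res$score_percent >= 0 && res$score_percent <= 100)
})

test_that("the external recognizer adapter round-trips the contract files", {
  toks <- small_tokens()
  refs <- toks$tokens[1:3]
  workdir <- withr::local_tempdir()
  ## fake recognizer: recognizes tokens whose id ends in an odd digit
  script <- file.path(workdir, "fake_asr.R")
  writeLines(c(
    "args <- commandArgs(trailingOnly = TRUE)",
    "m <- read.csv(args[[1]])",
    "odd <- as.integer(sub('.*(\\\\d)$', '\\\\1', m$token_id)) %% 2 == 1",
    "res <- data.frame(token_id = m$token_id, recognized = as.integer(odd),",
    "                  log_likelihood = ifelse(odd, -1.5, -9))",
    "write.csv(res, file.path(dirname(args[[1]]), 'result.csv'), row.names = FALSE)"
  ), script)
  res <- external_asr_score(refs, c("t1", "t2", "t3"), c("un", "deux", "trois"),
                            command = file.path(R.home("bin"), "Rscript"),
                            args = script, workdir = file.path(workdir, "run"))
  expect_equal(res$score_percent, 100 * 2 / 3)
  expect_equal(res$likelihood, -1.5)
  ## a command that writes nothing is an error
  bad <- file.path(workdir, "bad.R")
  writeLines("invisible(NULL)", bad)
  expect_error(
    external_asr_score(refs, c("t1", "t2", "t3"), c("a", "b", "c"),
                       command = file.path(R.home("bin"), "Rscript"),
                       args = bad, workdir = file.path(workdir, "run2")),
    "result.csv"
  )
})
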