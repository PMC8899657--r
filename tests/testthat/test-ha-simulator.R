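test_that("the channel filterbank localizes tones and reconstructs broadband input", {
  b <- channel_bank()
  ## 1-kHz tone lands in channel 2 (0.7-1.4 kHz)
  e <- vapply(filterbank_split(tone_signal(1000, 65), b),
              function(c) mean(c$samples^2), numeric(1))
  expect_gt(e[2] / sum(e), 0.95)
  ## white noise: the channel sum reconstructs the band-limited input
  set.seed(3)
  x <- calibrated_signal(rnorm(FS), FS)
  s <- Reduce(`+`, lapply(filterbank_split(x, b), function(c) c$samples))
  ref <- signal::filtfilt(signal::butter(4, 100 / (FS / 2), "high"), x$samples)
  expect_lt(10 * log10(mean((s - ref)^2) / mean(ref^2)), -30)
  ## silence in, silence out
  silent <- calibrated_signal(numeric(1000), FS)
  expect_true(all(vapply(filterbank_split(silent, b),
                         function(c) all(c$samples == 0), logical(1))))
  expect_error(filterbank_split(calibrated_signal(rnorm(100), 16000),
                                channel_bank(c(100, 700, 1400, 2800, 5600, 9000))),
               "undersampled")
})

test_that("the compressor realizes its static input/output curve", {
  p <- compressor_params(ct_db_spl = 40, cr = 2, gain_db = 20)
  ## below threshold: out = in + gain
  y <- compress_channel(tone_signal(1000, 30, 1), p)
  expect_equal(settled_level(y), 50, tolerance = 0.5)
  ## above threshold: out = ct + gain + (in - ct) / cr
  y <- compress_channel(tone_signal(1000, 60, 1), p)
  expect_equal(settled_level(y), 70, tolerance = 0.5)
  ## cr = 1 is a pure gain stage at any level
  lin <- compressor_params(ct_db_spl = 40, cr = 1, gain_db = 15)
  for (lev in c(20, 50, 80)) {
    y <- compress_channel(tone_signal(1000, lev, 0.6), lin)
    expect_equal(settled_level(y), lev + 15, tolerance = 0.5)
  }
  expect_error(compressor_params(40, 0.5), ">= 1")
})

test_that("the static curve is continuous at the threshold and monotone", {
  p <- compressor_params(ct_db_spl = 45, cr = 4, gain_db = 10)
  out <- vapply(c(44.95, 45.05), function(lev) {
    settled_level(compress_channel(tone_signal(500, lev, 1), p))
  }, numeric(1))
  expect_lt(abs(diff(out)), 0.3)  # no gain jump at CT
  levels_in <- seq(20, 90, 10)
  outs <- vapply(levels_in, function(lev) {
    settled_level(compress_channel(tone_signal(500, lev, 0.8), p))
  }, numeric(1))
  expect_true(all(diff(outs) > 0))
})

test_that("amplify is transparent for a zero-gain linear configuration", {
  b <- channel_bank()
  p0 <- baseline_prescription(flat_audiogram(0), b)
  toks <- small_tokens()
  x <- toks$tokens[[1]]
  y <- amplify(x, p0, b, block = 16)
  expect_equal(rms_level(y), rms_level(x), tolerance = 1)
})

test_that("amplify applies IGSP65 at the 65-dB operating point", {
  b <- channel_bank()
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  flat20 <- data.frame(frequency_hz = freqs, ig_sp65 = rep(20, 11),
                       ig_sp85 = rep(20, 11))  # CR = 1 everywhere
  p <- baseline_prescription(flat_audiogram(40), b, rule = "external",
                             table = flat20)
  set.seed(11)
  noise <- set_level(calibrated_signal(rnorm(FS), FS), 65)
  y <- amplify(noise, p, b, block = 16)
  expect_equal(rms_level(y), 85, tolerance = 1)
})

test_that("above threshold the two-point gain slope follows the compression ratio", {
  b <- channel_bank()
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  cr2 <- data.frame(frequency_hz = freqs, ig_sp65 = rep(20, 11),
                    ig_sp85 = rep(10, 11))  # 20 / (20 - 10) = 2
  p <- baseline_prescription(flat_audiogram(40), b, rule = "external",
                             table = cr2, ct_db_spl = rep(20, 5))
  set.seed(12)
  base <- rnorm(2 * FS)
  out <- vapply(c(65, 85), function(lev) {
    x <- set_level(calibrated_signal(base, FS), lev)
    settled_level(amplify(x, p, b, block = 16, limiter = NULL))
  }, numeric(1))
  expect_equal(out[2] - out[1], 10, tolerance = 1)
})

test_that("with linear channels and no limiter, amplify is a superposition", {
  b <- channel_bank()
  p0 <- baseline_prescription(flat_audiogram(0), b)
  t1 <- tone_signal(400, 60, 0.3)
  t2 <- tone_signal(2500, 60, 0.3)
  both <- calibrated_signal(t1$samples + t2$samples, FS)
  y1 <- amplify(t1, p0, b, block = 16, limiter = NULL)
  y2 <- amplify(t2, p0, b, block = 16, limiter = NULL)
  yb <- amplify(both, p0, b, block = 16, limiter = NULL)
  resid <- yb$samples - (y1$samples + y2$samples)
  expect_lt(mean(resid^2) / mean(yb$samples^2), 1e-4)
})

test_that("invalid configurations are rejected", {
  b <- channel_bank()
  p <- baseline_prescription(flat_audiogram(40), b)
  cfg <- ha_config(rep(35, 5), rep(0, 5), p)
  cfg$ct_db_spl[1] <- 10  # bypass the constructor check
  expect_error(amplify(small_tokens()$tokens[[1]], cfg, b), "constraint violation")
})
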