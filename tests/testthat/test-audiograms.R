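test_that("audiogram construction enforces the threshold invariants", {
  expect_error(audiogram(c(250, 250, 500), c(10, 20, 30)), "increasing")
  expect_error(flat_audiogram(130), "\\[-10, 120\\]")
  a <- audiogram(thresholds_db_hl = c(NA, rep(20, 10)))
  expect_s3_class(a, "audiogram")
  expect_true(anyNA(a$thresholds_db_hl))
})

test_that("cubic interpolation reproduces values lying on a cubic in log2(f)", {
  f <- audiogram(thresholds_db_hl = rep(0, 11))$frequencies_hz
  x <- log2(f)
  truth <- 5 + 3 * (x - 10) + 0.8 * (x - 10)^2 - 0.2 * (x - 10)^3
  thr <- truth
  held_out <- c(2, 5, 8, 10)
  thr[held_out] <- NA
  filled <- interpolate_missing_thresholds(audiogram(f, thr))
  expect_equal(filled$thresholds_db_hl[held_out], truth[held_out],
               tolerance = 1e-6)
  expect_equal(filled$thresholds_db_hl[-held_out], truth[-held_out])
})

test_that("a flat audiogram is completed with its constant value", {
  thr <- rep(40, 11)
  thr[c(1, 4, 6, 10)] <- NA
  filled <- interpolate_missing_thresholds(audiogram(thresholds_db_hl = thr))
  expect_equal(filled$thresholds_db_hl, rep(40, 11))
})

test_that("interpolated values equal an independent normal-equations solve", {
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  thr <- rep(NA_real_, 11)
  present <- match(c(500, 1000, 2000, 4000, 8000), freqs)
  thr[present] <- c(30, 40, 55, 70, 80)
  filled <- interpolate_missing_thresholds(audiogram(freqs, thr))
  ## oracle: degree-3 least squares via the design-matrix normal equations
  x <- log2(freqs[present])
  X <- cbind(1, x, x^2, x^3)
  beta <- solve(t(X) %*% X, t(X) %*% thr[present])
  xm <- log2(freqs[-present])
  expected <- pmin(pmax(as.numeric(cbind(1, xm, xm^2, xm^3) %*% beta), -10), 120)
  expect_equal(filled$thresholds_db_hl[-present], expected, tolerance = 1e-8)
  expect_equal(filled$thresholds_db_hl[present], thr[present])
})

test_that("interpolation refuses under-determined fits and is idempotent", {
  thr <- rep(NA_real_, 11)
  thr[c(3, 5, 7)] <- 40
  expect_error(interpolate_missing_thresholds(audiogram(thresholds_db_hl = thr)),
               "under-determined")
  complete <- flat_audiogram(25)
  expect_identical(interpolate_missing_thresholds(complete), complete)
})

test_that("the pure-tone average is the mean of the seven mid frequencies", {
  expect_equal(pta(flat_audiogram(40)), 40)
  expect_equal(pta(flat_audiogram(0)), 0)
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  thr <- rep(0, 11)
  thr[match(c(500, 750, 1000, 1500, 2000, 3000, 4000), freqs)] <-
    c(20, 25, 30, 35, 40, 45, 50)  # hand-summed mean: 245 / 7 = 35
  expect_equal(pta(audiogram(thresholds_db_hl = thr)), 35)
  incomplete <- audiogram(thresholds_db_hl = c(rep(20, 4), NA, rep(20, 6)))
  expect_error(pta(incomplete), "incomplete")
})

test_that("synthetic audiograms are seeded, ordered by severity, and valid", {
  expect_identical(synth_audiogram(4, seed = 1), synth_audiogram(4, seed = 1))
  expect_error(synth_audiogram(3, seed = 1), "invalid severity")
  ## severity ordering in expectation
  p4 <- mean(vapply(1:30, function(s) pta(synth_audiogram(4, s)), numeric(1)))
  p7 <- mean(vapply(1:30, function(s) pta(synth_audiogram(7, s)), numeric(1)))
  expect_gt(p7, p4)
  ## smooth profiles are monotonically non-decreasing
  a <- synth_audiogram(6, seed = 7, jitter = 0)
  expect_true(all(diff(a$thresholds_db_hl) >= 0))
  ## generator output always satisfies the audiogram invariants
  for (s in 1:10) {
    a <- synth_audiogram(sample(4:7, 1), seed = s, jitter = 5)
    expect_true(all(a$thresholds_db_hl >= -10 & a$thresholds_db_hl <= 120))
    expect_true(all(diff(a$frequencies_hz) > 0))
  }
})

test_that("audiogram CSV round-trips, including missing thresholds", {
  thr <- c(NA, 20, 30, NA, 40, 45, 55, 60, 70, NA, 80)
  a <- audiogram(thresholds_db_hl = thr, label = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_audiogram(a, path)
  b <- read_audiogram(path, label = "rt")
  expect_equal(b$thresholds_db_hl, thr)
  expect_equal(b$frequencies_hz, a$frequencies_hz)
})
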