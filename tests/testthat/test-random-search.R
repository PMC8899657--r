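test_that("the decrement schedule decays to the parameter stepsize", {
  s <- decay_schedule(10, 0.1, 750)
  expect_equal(eq2_delta(s, 0), 10)
  expect_equal(eq2_delta(s, 1), 10 - 9.9 / 750)
  expect_equal(eq2_delta(s, 750), 0.1)   # final range equals the stepsize
  expect_equal(eq2_delta(s, 10000), 0.1) # floored thereafter
  s_ct <- decay_schedule(15, 1, 750)
  expect_equal(eq2_delta(s_ct, 750), 1)
  expect_error(decay_schedule(0.1, 10), "initial_delta > stepsize")
  ## non-increasing in the step index
  d <- vapply(0:750, function(k) eq2_delta(s, k), numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("the linear-to-zero schedule hits zero at the terminal index", {
  s <- decay_schedule(15, 1, 750, mode = "eq3")
  expect_equal(eq3_delta(s, 749), 0)
  expect_equal(eq3_delta(s, 750), 0)  # floored
  expect_equal(eq3_delta(s, 375), 374 * 15 / 750)
  h <- decay_schedule(10, 0.1, 750, mode = "eq3")
  expect_equal(eq3_delta(h, 1), 748 * 10 / 750)
  expect_error(eq3_delta(s, 0), "out of range")
  expect_error(eq3_delta(s, 751), "out of range")
  d <- vapply(1:750, function(i) eq3_delta(s, i), numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("acceptance requires a strict improvement, with a likelihood tie-break", {
  expect_true(accept_candidate(list(score = 90, likelihood = -1),
                               list(score = 92, likelihood = -5)))
  expect_true(accept_candidate(list(score = 90, likelihood = -1),
                               list(score = 90, likelihood = -0.5)))
  expect_false(accept_candidate(list(score = 90, likelihood = -1),
                                list(score = 90, likelihood = -1)))
  expect_false(accept_candidate(list(score = 90, likelihood = -1),
                                list(score = 88, likelihood = 10)))
})

quad_opt <- list(dig = c(3.2, -5.1, 7.4, 0.3, -2.2),
                 ct_db_spl = c(24, 41, 33, 47, 28))

test_that("searches are bit-reproducible for a fixed seed", {
  obj <- make_quadratic_objective(quad_opt)
  for (runner in list(function(s) gen1_run(obj, budget = 30, seed = s),
                      function(s) gen2_run(obj, budget = 50, seed = s),
                      function(s) gen3_run(obj, ct_budget = 10, ig_budget = 20,
                                           seed = s))) {
    r1 <- runner(7)
    r2 <- runner(7)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best_dig, r2$best_dig)
    r3 <- runner(8)
    expect_false(identical(r1$trace, r3$trace))
  }
})

test_that("best-score traces never decrease and candidates stay on the grid", {
  obj <- make_quadratic_objective(quad_opt)
  runs <- list(gen1_run(obj, budget = 60, seed = 2),
               gen2_run(obj, budget = 100, seed = 2),
               gen3_run(obj, ct_budget = 30, ig_budget = 60, seed = 2))
  for (st in runs) {
    tr <- st$trace
    if (st$algorithm == "gen1") {
      for (t in unique(tr$thread)) {
        expect_true(all(diff(tr$best_score[tr$thread == t]) >= 0))
      }
    } else {
      expect_true(all(diff(tapply(tr$best_score, tr$iteration, max)) >= 0))
    }
    digs <- as.matrix(tr[paste0("dig_", 1:5)])
    cts <- as.matrix(tr[paste0("ct_", 1:5)])
    expect_true(all(digs >= -10 & digs <= 10))
    expect_true(all(cts >= 20 & cts <= 50))
    expect_true(all(abs(digs * 10 - round(digs * 10)) < 1e-9))
    expect_true(all(abs(cts - round(cts)) < 1e-9))
    ## the returned best dominates every evaluation in the trace
    best <- st$best_result
    expect_true(all(tr$score < best$score_percent |
                      (tr$score == best$score_percent &
                         tr$likelihood <= best$likelihood)))
  }
})

test_that("a degenerate budget returns the best of the thread initializations", {
  obj <- make_quadratic_objective(quad_opt)
  st <- gen1_run(obj, budget = 1, seed = 5)
  inits <- st$trace[st$trace$iteration == 0, ]
  expect_equal(nrow(inits), 4)
  expect_gte(st$best_result$likelihood, max(inits$likelihood))
  expect_gte(st$best_result$score_percent, max(inits$score))
})

test_that("GEN2 consumes 150 iterations per channel and freezes tuned channels", {
  obj <- make_quadratic_objective(quad_opt)
  st <- gen2_run(obj, budget = 750, seed = 3)
  tr <- st$trace
  iters <- tr[tr$iteration >= 1 & !grepl("init", tr$channel_phase), ]
  expect_equal(max(iters$iteration), 750)
  expect_equal(sum(iters$thread == 1), 750)  # 5 x 150 per thread
  ## during the channel-3 phase, channels 1-2 are frozen and 4-5 at baseline
  ph3 <- tr[tr$channel_phase == "ch3" & tr$thread == 1, ]
  expect_equal(length(unique(ph3$dig_4)), 1)
  expect_equal(length(unique(ph3$dig_5)), 1)
  expect_true(length(unique(ph3$dig_3)) > 1)
})

test_that("GEN3 pins gain offsets during its threshold phase", {
  obj <- make_quadratic_objective(quad_opt)
  st <- gen3_run(obj, ct_budget = 40, ig_budget = 80, seed = 3)
  tr <- st$trace
  ct_phase <- tr[grepl("^ct", tr$channel_phase), ]
  digs <- as.matrix(ct_phase[paste0("dig_", 1:5)])
  expect_true(all(digs == 0))  # zero IG-offset variation while CTs are tuned
  ig_phase <- tr[grepl("^ig", tr$channel_phase), ]
  cts <- as.matrix(ig_phase[paste0("ct_", 1:5)])
  expect_true(all(apply(cts, 2, function(v) length(unique(v))) == 1))
})

test_that("all three algorithms recover a hidden optimum at full budget", {
  obj <- make_quadratic_objective(quad_opt)
  runs <- list(gen1 = gen1_run(obj, budget = 750, seed = 1),
               gen2 = gen2_run(obj, budget = 750, seed = 1),
               gen3 = gen3_run(obj, seed = 1))
  for (st in runs) {
    expect_true(all(abs(st$best_dig - quad_opt$dig) <= 5 * 0.1))
    expect_true(all(abs(st$best_ct - quad_opt$ct_db_spl) <= 5 * 1))
  }
})

test_that("random search matches exhaustive enumeration on a coarse toy grid", {
  ## toy sub-grid on channel 1 (5 gain values x 3 thresholds), other
  ## channels held at the optimum: enumeration oracle vs gen1
  opt <- list(dig = c(2.7, 0, 0, 0, 0), ct_db_spl = c(38, 35, 35, 35, 35))
  obj <- make_quadratic_objective(opt)
  grid <- expand.grid(dig1 = c(-10, -5, 0, 5, 10), ct1 = c(20, 35, 50))
  best_enum <- NULL
  for (k in seq_len(nrow(grid))) {
    r <- obj$evaluate(c(grid$dig1[k], opt$dig[-1]),
                      c(grid$ct1[k], opt$ct_db_spl[-1]))
    if (is.null(best_enum) || accept_candidate(best_enum, r)) best_enum <- r
  }
  st <- gen1_run(obj, budget = 200, seed = 4)
  ## the search reaches at least the enumerated optimum of the coarse grid
  sc <- st$best_result$score_percent
  expect_true(sc > best_enum$score_percent ||
                (sc == best_enum$score_percent &&
                   st$best_result$likelihood >= best_enum$likelihood))
})

test_that("the search-space count reproduces the full-grid figure", {
  expect_equal(count_search_space(), 6000^5)
  expect_equal(count_search_space(), 7.776e18)
  expect_equal(count_search_space(ig_span = 0.2, ig_step = 0.1,
                                  ct_span = 3, ct_step = 1, n_channels = 1), 6)
  expect_equal(count_search_space(n_channels = 0), 1)  # empty product
  expect_error(count_search_space(ig_span = 20, ig_step = 0.3), "invalid grid")
})
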