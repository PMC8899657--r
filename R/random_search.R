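## The three genetic random-search algorithms: decaying search ranges,
## four search threads, rollback acceptance with a likelihood tie-break.

#' Decay schedule for a search half-range
#'
#' Two decay laws for the half-range `Delta_P` explored around the best
#' value of a parameter `P` over a fixed iteration budget:
#' \describe{
#'   \item{`"eq2"`}{a constant per-iteration decrement,
#'     `Delta_{i+1} = Delta_i - (initial - stepsize) / total`, so the range
#'     explored during the final iteration equals the parameter stepsize
#'     (the value is floored there).}
#'   \item{`"eq3"`}{linear shrink to zero,
#'     `Delta_i = (total - i - 1) * half_range / total`, floored at 0.}
#' }
#'
#' @param initial_delta Initial half-range in dB (half the search range).
#' @param stepsize Parameter variation step in dB (0.1 for gains, 1 for
#'   compression thresholds).
#' @param total_iterations Iteration budget (default 750).
#' @param mode `"eq2"` (decrement) or `"eq3"` (linear-to-zero).
#' @param half_range Half-range for `"eq3"`; defaults to `initial_delta`.
#' @return An object of class `decay_schedule`.
#' @export
decay_schedule <- function(initial_delta, stepsize, total_iterations = 750,
                           mode = c("eq2", "eq3"), half_range = initial_delta) {
  mode <- match.arg(mode)
  if (!(initial_delta > stepsize && stepsize > 0)) {
    stop("need initial_delta > stepsize > 0", call. = FALSE)
  }
  if (total_iterations < 1) stop("total_iterations must be >= 1", call. = FALSE)
  structure(list(initial_delta = initial_delta, stepsize = stepsize,
                 total_iterations = total_iterations, mode = mode,
                 half_range = half_range),
            class = "decay_schedule")
}

#' Search half-range under the decrement schedule
#'
#' @param schedule A `"eq2"` [decay_schedule()].
#' @param steps_applied Number of per-iteration decrements applied so far.
#' @return Half-range in dB, floored at the parameter stepsize.
#' @export
#' @examples
#' s <- decay_schedule(10, 0.1)
#' eq2_delta(s, 750)  # the stepsize, 0.1
eq2_delta <- function(schedule, steps_applied) {
  stopifnot(inherits(schedule, "decay_schedule"), schedule$mode == "eq2")
  d <- schedule$initial_delta -
    steps_applied * (schedule$initial_delta - schedule$stepsize) /
      schedule$total_iterations
  max(d, schedule$stepsize)
}

#' Search half-range under the linear-to-zero schedule
#'
#' @param schedule A `"eq3"` [decay_schedule()].
#' @param i Iteration index, 1 to `total_iterations`.
#' @return Half-range in dB, floored at 0.
#' @export
eq3_delta <- function(schedule, i) {
  stopifnot(inherits(schedule, "decay_schedule"), schedule$mode == "eq3")
  if (i < 1 || i > schedule$total_iterations) {
    stop("iteration index out of range", call. = FALSE)
  }
  max((schedule$total_iterations - i - 1) * schedule$half_range /
        schedule$total_iterations, 0)
}

result_score <- function(r) if (!is.null(r$score_percent)) r$score_percent else r$score
result_lik <- function(r) r$likelihood

#' Rollback acceptance rule
#'
#' A candidate replaces the incumbent only if it scores strictly higher, or
#' scores equally and has a strictly higher likelihood; otherwise the search
#' rolls back to the incumbent. Exact ties on both keep the incumbent.
#'
#' @param incumbent,candidate [intelligibility_result()] objects (or lists
#'   with `score`/`score_percent` and `likelihood`).
#' @return `TRUE` to accept the candidate, `FALSE` to roll back.
#' @export
accept_candidate <- function(incumbent, candidate) {
  si <- result_score(incumbent); sc <- result_score(candidate)
  sc > si || (sc == si && result_lik(candidate) > result_lik(incumbent))
}

## Global parameter ranges and stepsizes of the search space.
PARAM_SPACE <- list(
  dig = list(lo = -10, hi = 10, step = 0.1, half = 10),
  ct  = list(lo = 20,  hi = 50, step = 1,   half = 15)
)

draw_uniform <- function(n, sp) {
  clamp(round_to_step(runif(n, sp$lo, sp$hi), sp$step), sp$lo, sp$hi)
}

perturb <- function(center, delta, sp) {
  clamp(round_to_step(center + runif(length(center), -delta, delta), sp$step),
        sp$lo, sp$hi)
}

## ---- trace recorder ------------------------------------------------------

new_trace <- function(n, nch) {
  env <- new.env(parent = emptyenv())
  env$m <- matrix(NA_real_, n, 2 * nch + 4)
  env$thread <- integer(n); env$phase <- character(n); env$acc <- logical(n)
  env$k <- 0L
  env
}

trace_add <- function(tr, thread, iteration, phase, dig, ct, score, lik,
                      accepted, best_score) {
  tr$k <- tr$k + 1L
  tr$m[tr$k, ] <- c(iteration, ct, dig, score, lik, best_score)
  tr$thread[tr$k] <- thread
  tr$phase[tr$k] <- phase
  tr$acc[tr$k] <- accepted
}

trace_df <- function(tr, algorithm, nch) {
  k <- seq_len(tr$k)
  m <- tr$m[k, , drop = FALSE]
  out <- data.frame(algorithm = algorithm, thread = tr$thread[k],
                    iteration = as.integer(m[, 1]), channel_phase = tr$phase[k])
  ctc <- as.data.frame(m[, 1 + seq_len(nch), drop = FALSE])
  names(ctc) <- paste0("ct_", seq_len(nch))
  digc <- as.data.frame(m[, 1 + nch + seq_len(nch), drop = FALSE])
  names(digc) <- paste0("dig_", seq_len(nch))
  cbind(out, ctc, digc,
        data.frame(score = m[, 2 * nch + 2], likelihood = m[, 2 * nch + 3],
                   accepted = tr$acc[k], best_score = m[, 2 * nch + 4]))
}

search_state <- function(algorithm, best, trace, seed, iterations) {
  structure(list(algorithm = algorithm,
                 best_dig = best$dig, best_ct = best$ct,
                 best_result = best$res,
                 best_config = attr(best$res, "config"),
                 trace = trace, seed = seed, iterations = iterations),
            class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  cat(sprintf("%s search (%d iterations): best score %.1f%% (likelihood %.4f)\n",
              toupper(x$algorithm), x$iterations,
              result_score(x$best_result), result_lik(x$best_result)))
  cat("  dig:", paste(sprintf("%+.1f", x$best_dig), collapse = " "), "dB\n")
  cat("  ct: ", paste(sprintf("%.0f", x$best_ct), collapse = "  "), "dB SPL\n")
  invisible(x)
}

thread_seeds <- function(seed, threads) {
  with_local_seed(seed, sample.int(2^30, threads + 1L))
}

#' GEN1: simultaneous tuning in four independent threads
#'
#' Four independent search threads each start from a random configuration
#' (uniform over the full parameter ranges) and, at every iteration, perturb
#' all per-channel gain offsets and compression thresholds within the
#' decrement-schedule half-ranges around the thread's best configuration.
#' Non-improving candidates are rolled back ([accept_candidate()]); after
#' the budget is spent the best configuration across threads is returned.
#' Fully reproducible for a fixed seed.
#'
#' @param objective An `rs_objective` (see [make_surrogate_objective()],
#'   [make_quadratic_objective()]).
#' @param budget Iterations per thread (default 750).
#' @param threads Number of search threads (default 4). Threads are
#'   deterministic sequential workers with independent seeded RNG streams;
#'   results do not depend on physical concurrency.
#' @param seed Integer seed.
#' @param init Optional list with `dig` and `ct_db_spl`: a configuration
#'   used to initialize thread 1 in place of its random draw (used by
#'   [run_experiment()] to seed the search with the baseline fitting).
#' @return A `search_state`: best configuration (`best_dig`, `best_ct`),
#'   its [intelligibility_result()], and the full evaluation `trace`.
#' @export
gen1_run <- function(objective, budget = 750, threads = 4, seed = 1,
                     init = NULL) {
  ig_sched <- decay_schedule(PARAM_SPACE$dig$half, PARAM_SPACE$dig$step, budget)
  ct_sched <- decay_schedule(PARAM_SPACE$ct$half, PARAM_SPACE$ct$step, budget)
  seeds <- thread_seeds(seed, threads)
  tr <- new_trace(threads * (budget + 1L), 5L)
  best <- NULL
  for (t in seq_len(threads)) {
    stream <- rng_stream(seeds[t])
    if (t == 1L && !is.null(init)) {
      dig <- init$dig; ct <- init$ct_db_spl
    } else {
      dig <- stream$draw(draw_uniform(5, PARAM_SPACE$dig))
      ct <- stream$draw(draw_uniform(5, PARAM_SPACE$ct))
    }
    res <- objective$evaluate(dig, ct)
    cur <- list(dig = dig, ct = ct, res = res)
    trace_add(tr, t, 0L, "all", dig, ct, result_score(res), result_lik(res),
              TRUE, result_score(res))
    for (i in seq_len(budget)) {
      d_ig <- eq2_delta(ig_sched, i - 1)
      d_ct <- eq2_delta(ct_sched, i - 1)
      dig_c <- stream$draw(perturb(cur$dig, d_ig, PARAM_SPACE$dig))
      ct_c <- stream$draw(perturb(cur$ct, d_ct, PARAM_SPACE$ct))
      res_c <- objective$evaluate(dig_c, ct_c)
      acc <- accept_candidate(cur$res, res_c)
      if (acc) cur <- list(dig = dig_c, ct = ct_c, res = res_c)
      trace_add(tr, t, i, "all", dig_c, ct_c, result_score(res_c),
                result_lik(res_c), acc, result_score(cur$res))
    }
    if (is.null(best) || accept_candidate(best$res, cur$res)) best <- cur
  }
  search_state("gen1", best, trace_df(tr, "gen1", 5L), seed, budget)
}

## Shared machinery for the synchronized algorithms (GEN2/GEN3): every
## iteration all threads draw a candidate around the cross-thread best; the
## best of the thread candidates (strict acceptance, lowest thread index on
## exact ties) challenges the incumbent.
sync_round <- function(threads, make_candidate, evaluate, incumbent, tr,
                       iteration, phase) {
  round_best <- NULL
  for (t in seq_len(threads)) {
    cand <- make_candidate(t)
    res <- evaluate(cand$dig, cand$ct)
    cand$res <- res
    if (is.null(round_best) || accept_candidate(round_best$res, res)) {
      round_best <- cand
    }
    acc_inc <- if (is.null(incumbent)) TRUE else accept_candidate(incumbent$res, res)
    trace_add(tr, t, iteration, phase, cand$dig, cand$ct,
              result_score(res), result_lik(res), acc_inc,
              if (is.null(incumbent)) result_score(res)
              else max(result_score(incumbent$res), result_score(res)))
  }
  if (is.null(incumbent) || accept_candidate(incumbent$res, round_best$res)) {
    round_best
  } else {
    incumbent
  }
}

#' GEN2: channel-by-channel tuning with synchronized threads
#'
#' Channels are tuned in order 1 to 5, each for `budget / 5` iterations. At
#' each iteration the four threads draw the active channel's gain offset and
#' compression threshold uniformly within the linear-to-zero half-ranges
#' (global iteration index) around the cross-thread best configuration;
#' previously tuned channels stay frozen at their best values and untuned
#' channels sit at the baseline prescription with the default compression
#' threshold (35 dB SPL). Each channel phase starts with a random
#' initialization of the active channel in every thread.
#'
#' @inheritParams gen1_run
#' @param budget Total iterations, split evenly over the 5 channels
#'   (default 750, i.e. 150 per channel).
#' @return A `search_state`.
#' @export
gen2_run <- function(objective, budget = 750, threads = 4, seed = 1,
                     init = NULL) {
  nch <- 5L
  if (budget %% nch != 0) stop("budget must divide evenly over 5 channels", call. = FALSE)
  per <- budget %/% nch
  ig_sched <- decay_schedule(PARAM_SPACE$dig$half, PARAM_SPACE$dig$step, budget,
                             mode = "eq3")
  ct_sched <- decay_schedule(PARAM_SPACE$ct$half, PARAM_SPACE$ct$step, budget,
                             mode = "eq3")
  seeds <- thread_seeds(seed, threads)
  streams <- lapply(seeds[seq_len(threads)], rng_stream)
  tr <- new_trace(threads * (budget + nch) + 1L, nch)
  incumbent <- NULL
  base_dig <- rep(0, nch)
  base_ct <- rep(35, nch)
  if (!is.null(init)) {
    res0 <- objective$evaluate(init$dig, init$ct_db_spl)
    incumbent <- list(dig = init$dig, ct = init$ct_db_spl, res = res0)
    trace_add(tr, 0L, 0L, "init", init$dig, init$ct_db_spl,
              result_score(res0), result_lik(res0), TRUE, result_score(res0))
  }
  for (ch in seq_len(nch)) {
    carrier <- if (is.null(incumbent)) list(dig = base_dig, ct = base_ct) else incumbent
    incumbent <- sync_round(
      threads,
      function(t) {
        dig <- carrier$dig; ct <- carrier$ct
        dig[ch] <- streams[[t]]$draw(draw_uniform(1, PARAM_SPACE$dig))
        ct[ch] <- streams[[t]]$draw(draw_uniform(1, PARAM_SPACE$ct))
        list(dig = dig, ct = ct)
      },
      objective$evaluate, incumbent, tr, (ch - 1L) * per,
      paste0("ch", ch, "-init")
    )
    for (i in ((ch - 1L) * per + 1L):(ch * per)) {
      d_ig <- eq3_delta(ig_sched, i)
      d_ct <- eq3_delta(ct_sched, i)
      incumbent <- sync_round(
        threads,
        function(t) {
          dig <- incumbent$dig; ct <- incumbent$ct
          dig[ch] <- streams[[t]]$draw(perturb(incumbent$dig[ch], d_ig, PARAM_SPACE$dig))
          ct[ch] <- streams[[t]]$draw(perturb(incumbent$ct[ch], d_ct, PARAM_SPACE$ct))
          list(dig = dig, ct = ct)
        },
        objective$evaluate, incumbent, tr, i, paste0("ch", ch)
      )
    }
  }
  search_state("gen2", list(dig = incumbent$dig, ct = incumbent$ct,
                            res = incumbent$res),
               trace_df(tr, "gen2", nch), seed, budget)
}

#' GEN3: compression thresholds first, then gains, in all channels
#'
#' Phase 1 tunes the five compression thresholds for `ct_budget` iterations
#' with the gain offsets pinned to the baseline prescription (zero offset);
#' phase 2 tunes the five gain offsets for `ig_budget` iterations with the
#' thresholds frozen at the phase-1 best. Threads are synchronized on the
#' cross-thread best as in [gen2_run()], and the linear-to-zero half-ranges
#' use the global iteration index over the combined budget.
#'
#' @inheritParams gen1_run
#' @param ct_budget Iterations for the threshold phase (default 250).
#' @param ig_budget Iterations for the gain phase (default 500).
#' @return A `search_state`.
#' @export
gen3_run <- function(objective, ct_budget = 250, ig_budget = 500, threads = 4,
                     seed = 1, init = NULL) {
  nch <- 5L
  total <- ct_budget + ig_budget
  ig_sched <- decay_schedule(PARAM_SPACE$dig$half, PARAM_SPACE$dig$step, total,
                             mode = "eq3")
  ct_sched <- decay_schedule(PARAM_SPACE$ct$half, PARAM_SPACE$ct$step, total,
                             mode = "eq3")
  seeds <- thread_seeds(seed, threads)
  streams <- lapply(seeds[seq_len(threads)], rng_stream)
  tr <- new_trace(threads * (total + 2L) + 1L, nch)
  incumbent <- NULL
  if (!is.null(init)) {
    res0 <- objective$evaluate(init$dig, init$ct_db_spl)
    incumbent <- list(dig = init$dig, ct = init$ct_db_spl, res = res0)
    trace_add(tr, 0L, 0L, "init", init$dig, init$ct_db_spl,
              result_score(res0), result_lik(res0), TRUE, result_score(res0))
  }
  base_dig <- rep(0, nch)
  ## phase 1: CTs, gains pinned to baseline
  carrier_ct <- if (is.null(incumbent)) rep(35, nch) else incumbent$ct
  incumbent <- sync_round(
    threads,
    function(t) list(dig = base_dig,
                     ct = streams[[t]]$draw(draw_uniform(nch, PARAM_SPACE$ct))),
    objective$evaluate, incumbent, tr, 0L, "ct-init"
  )
  for (i in seq_len(ct_budget)) {
    d_ct <- eq3_delta(ct_sched, i)
    incumbent <- sync_round(
      threads,
      function(t) list(dig = incumbent$dig,
                       ct = streams[[t]]$draw(perturb(incumbent$ct, d_ct,
                                                      PARAM_SPACE$ct))),
      objective$evaluate, incumbent, tr, i, "ct"
    )
  }
  ## phase 2: gain offsets, CTs frozen at the phase-1 best
  ct_frozen <- incumbent$ct
  incumbent <- sync_round(
    threads,
    function(t) list(dig = streams[[t]]$draw(draw_uniform(nch, PARAM_SPACE$dig)),
                     ct = ct_frozen),
    objective$evaluate, incumbent, tr, ct_budget, "ig-init"
  )
  for (i in (ct_budget + 1L):total) {
    d_ig <- eq3_delta(ig_sched, i)
    incumbent <- sync_round(
      threads,
      function(t) list(dig = streams[[t]]$draw(perturb(incumbent$dig, d_ig,
                                                       PARAM_SPACE$dig)),
                       ct = incumbent$ct),
      objective$evaluate, incumbent, tr, i, "ig"
    )
  }
  search_state("gen3", list(dig = incumbent$dig, ct = incumbent$ct,
                            res = incumbent$res),
               trace_df(tr, "gen3", nch), seed, total)
}

#' Size of the discrete search space
#'
#' Number of distinct hearing-aid configurations on the search grid: the
#' product over channels of the number of gain-offset values times the
#' number of compression-threshold values, ranges counted half-open
#' (`span / step` values per parameter).
#'
#' @param bank A [channel_bank()] (only its channel count is used).
#' @param ig_span,ig_step Gain-offset range width and step in dB.
#' @param ct_span,ct_step Compression-threshold range width and step in dB.
#' @param n_channels Number of channels (default: from `bank`).
#' @return The configuration count (as a double).
#' @export
#' @examples
#' count_search_space()  # 6000^5 = 7.776e18
count_search_space <- function(bank = channel_bank(), ig_span = 20,
                               ig_step = 0.1, ct_span = 30, ct_step = 1,
                               n_channels = bank$n_channels) {
  n_ig <- ig_span / ig_step
  n_ct <- ct_span / ct_step
  if (abs(n_ig - round(n_ig)) > 1e-9 || abs(n_ct - round(n_ct)) > 1e-9) {
    stop("invalid grid: spans must be multiples of their steps", call. = FALSE)
  }
  (round(n_ig) * round(n_ct))^n_channels
}
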