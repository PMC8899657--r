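## Small shared helpers. None exported.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Round to the nearest multiple of `step` (stepped parameter grids).
round_to_step <- function(x, step) round(x / step) * step

## Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

## A resumable RNG stream: draws restore/save .Random.seed around each call so
## several streams can interleave deterministically (the "thread" semantics of
## the search algorithms are independent of physical concurrency).
rng_stream <- function(seed) {
  state <- with_local_seed(seed, {
    runif(1)  # advance once so distinct seeds diverge immediately
    get(".Random.seed", envir = globalenv())
  })
  draw <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    assign(".Random.seed", state, envir = globalenv())
    res <- force(expr)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    res
  }
  list(draw = function(expr) draw(expr))
}

db_to_lin <- function(db) 10^(db / 20)
lin_to_db <- function(lin) 20 * log10(pmax(lin, .Machine$double.xmin))

## Interpolate a threshold curve at arbitrary frequencies, linear in log2(f),
## constant extrapolation beyond the tabulated range.
interp_log2 <- function(freq_tab, val_tab, freq_out) {
  approx(log2(freq_tab), val_tab, xout = log2(freq_out), rule = 2)$y
}
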