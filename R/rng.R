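#' Derive a named component seed from a global run seed
#'
#' One global seed fans out to named per-component streams (env, policy,
#' predictor, planner, ...) so a component can be ablated without
#' perturbing the draws of the others. The result is always a valid 32-bit
#' integer seed.
#'
#' @param seed Integer base seed.
#' @param name Stream name.
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 1014731
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' An isolated RNG stream
#'
#' Wraps R's Mersenne-Twister state so that draws from this stream do not
#' disturb (and are not disturbed by) the global RNG or other streams.
#'
#' @param seed Integer seed for the stream.
#' @return A list of drawing functions: `rnorm(n, mean, sd)`,
#'   `runif(n, min, max)`, `sample_int(lo, hi)` (one uniform integer).
#' @export
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- expr()
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    sample_int = function(lo, hi)
      with_state(function() lo + floor(stats::runif(1) * (hi - lo + 1)))
  )
}
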