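`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and a stage tag
#'
#' Deterministically maps `(seed, tag)` to an integer in `[1, 2^31 - 2]` so
#' that every randomized stage of a pipeline gets its own reproducible
#' stream from one global seed.
#'
#' @param seed Integer parent seed.
#' @param tag Character tag naming the consumer (e.g. `"augment"`).
#' @return Integer scalar seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (cc in utf8ToInt(as.character(tag))) h <- (h * 131 + cc) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 7919 + h) %% 2147483629 + 1)
}

# A self-contained RNG stream: draws reproduce set.seed(seed) order without
# touching (or being affected by) the caller's .Random.seed.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    genv <- globalenv()
    old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
      get(".Random.seed", envir = genv) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = genv)
    res <- f()
    state <<- get(".Random.seed", envir = genv)
    if (is.null(old)) rm(".Random.seed", envir = genv)
    else assign(".Random.seed", old, envir = genv)
    res
  }
  list(
    sample = function(n, size = n, replace = FALSE, prob = NULL)
      run(function() sample.int(n, size, replace, prob)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) run(function() stats::rbinom(n, size, prob)),
    with = run)
}

# Half-away-from-zero rounding, matching the table style used in reports.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample standard deviation with N-1 denominator, NA-free
sd1 <- function(x) stats::sd(x)
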