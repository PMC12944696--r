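# Shared fixtures, built in code and memoised per test run.

small_task_cache <- new.env(parent = emptyenv())

# A small end-to-end task (4 synthetic records x 30 beats) for pipeline and
# training tests; the full-size toy task is built only in the acceptance
# suite.
small_toy_task <- function() {
  if (is.null(small_task_cache$task)) {
    small_task_cache$task <- make_toy_task(
      toy_dataset_spec(n_records = 4L, beats_per_record = 30L, seed = 101L),
      toy_model_config(seed = 101L), seed = 101L)
  }
  small_task_cache$task
}

small_noise_bank <- function(fs = 360, n = 50000, seed = 7L) {
  if (is.null(small_task_cache$bank)) {
    small_task_cache$bank <- noise_bank(synth_em_noise(n, fs, seed = seed), fs)
  }
  small_task_cache$bank
}

# a clean fixture record with ground-truth R indices
fixture_record <- function(hr = 70, n_beats = 40, frac = 0.3, seed = 5L) {
  synth_record_set(toy_dataset_spec(n_records = 1L, beats_per_record = n_beats,
                                    arrhythmia_fraction = frac,
                                    heart_rate_bpm = c(hr, hr),
                                    seed = seed))[[1]]
}

# independent scalar bilinear interpolation (align-corners), used as the
# oracle for the vectorized resize
bilinear_point <- function(V, r, c) {
  m <- nrow(V); n <- ncol(V)
  lo_r <- min(floor(r), m - 1); fr_r <- r - lo_r
  lo_c <- min(floor(c), n - 1); fr_c <- c - lo_c
  V[lo_r, lo_c] * (1 - fr_r) * (1 - fr_c) +
    V[lo_r + 1, lo_c] * fr_r * (1 - fr_c) +
    V[lo_r, lo_c + 1] * (1 - fr_r) * fr_c +
    V[lo_r + 1, lo_c + 1] * fr_r * fr_c
}

# finite-difference gradient check harness for a scalar loss over a layer
grad_check_layer <- function(layer, x, loss_weights = NULL, eps = 1e-5,
                             n_checks = 5, seed = 1) {
  lw <- loss_weights
  loss_of <- function(out) {
    if (is.null(lw)) sum(out^2) / 2 else sum(out * lw)
  }
  out <- layer$forward(x, train = TRUE)
  dout <- if (is.null(lw)) out else lw
  if (is.null(dim(dout))) dout <- array(dout, dim = dim(out) %||% length(out))
  zero_grads_test(layer$params())
  dx <- layer$backward(dout)
  worst <- 0
  set.seed(seed)
  # parameter gradients
  for (p in layer$params()) {
    for (k in sample(length(p$value), min(n_checks, length(p$value)))) {
      v0 <- p$value[k]
      p$value[k] <- v0 + eps
      lp <- loss_of(layer$forward(x, train = TRUE))
      p$value[k] <- v0 - eps
      lm <- loss_of(layer$forward(x, train = TRUE))
      p$value[k] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - p$grad[k]) /
                     max(1e-6, abs(num) + abs(p$grad[k])))
    }
  }
  # input gradients
  for (k in sample(length(x), min(n_checks, length(x)))) {
    v0 <- x[k]
    x[k] <- v0 + eps
    lp <- loss_of(layer$forward(x, train = TRUE))
    x[k] <- v0 - eps
    lm <- loss_of(layer$forward(x, train = TRUE))
    x[k] <- v0
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - dx[k]) / max(1e-6, abs(num) + abs(dx[k])))
  }
  worst
}

zero_grads_test <- function(params) {
  for (p in params)
    p$grad <- array(0, dim = dim(p$value) %||% length(p$value))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
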