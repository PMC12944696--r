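#' Standard gravity used for unit conversion (m/s^2 per g)
#' @export
G_ACCEL <- 9.80665

#' Accelerometer magnitude
#'
#' Per-sample Euclidean norm of a tri-axial accelerometer signal.
#'
#' @param a 3 x N numeric matrix (rows = x, y, z in m/s^2).
#' @return Numeric vector of length N.
#' @export
accel_magnitude <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != 3L) stop("accelerometer array must have 3 rows (x, y, z)")
  sqrt(colSums(a^2))
}

#' Windowed statistical motion features
#'
#' Splits the signal into non-overlapping windows (the last partial window is
#' dropped) and computes, per window: the mean magnitude, the N-1 standard
#' deviation of the magnitude, and the signal magnitude area
#' `SMA = mean(|ax| + |ay| + |az|)`.
#'
#' @param a 3 x N accelerometer matrix (m/s^2).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 2).
#' @return Data frame with columns `t_start`, `mu`, `sigma`, `sma`
#'   (one row per complete window).
#' @export
accel_window_stats <- function(a, fs, window_s = 2) {
  a <- as.matrix(a)
  if (nrow(a) != 3L) stop("accelerometer array must have 3 rows")
  w <- round(fs * window_s)
  if (w < 2) stop("window must contain at least 2 samples")
  mag <- accel_magnitude(a)
  n_win <- length(mag) %/% w
  if (n_win == 0)
    return(data.frame(t_start = numeric(0), mu = numeric(0),
                      sigma = numeric(0), sma = numeric(0)))
  out <- t(vapply(seq_len(n_win), function(i) {
    ix <- ((i - 1) * w + 1):(i * w)
    c(mu = mean(mag[ix]),
      sigma = stats::sd(mag[ix]),
      sma = mean(colSums(abs(a[, ix, drop = FALSE]))))
  }, numeric(3)))
  data.frame(t_start = (seq_len(n_win) - 1) * window_s,
             mu = out[, "mu"], sigma = out[, "sigma"], sma = out[, "sma"])
}

#' Spectral motion features
#'
#' Dominant frequency and spectral entropy of the accelerometer magnitude.
#' The mean is removed before the transform and the DC bin is excluded from
#' the dominant-frequency argmax (it would otherwise always win for any
#' signal with residual offset).  Entropy is computed over the normalized
#' one-sided power spectrum, in bits.
#'
#' @param mag Magnitude signal (length >= 8).
#' @param fs Sampling rate in Hz.
#' @return List with `f_dom` (Hz) and `entropy_bits`.  An all-zero (or
#'   constant) window returns `f_dom = 0`, `entropy_bits = 0`.
#' @export
accel_spectral_features <- function(mag, fs) {
  n <- length(mag)
  if (n < 8) stop("need at least 8 samples for spectral features")
  v <- mag - mean(mag)
  if (all(abs(v) < 1e-14)) return(list(f_dom = 0, entropy_bits = 0))
  P <- Mod(stats::fft(v))^2
  K <- n %/% 2 + 1L
  P <- P[seq_len(K)]
  freqs <- (0:(K - 1)) * fs / n
  P[1] <- 0                       # DC excluded
  p <- P / sum(P)
  nz <- p > 0
  H <- -sum(p[nz] * log2(p[nz]))
  list(f_dom = freqs[which.max(P)], entropy_bits = H)
}

#' Motion-intensity class from magnitude variability
#'
#' Classifies a window into Rest / Light / Moderate / Vigorous from the
#' standard deviation of the accelerometer magnitude expressed in g, with
#' thresholds 0.1, 0.3 and 0.6 g (each boundary belonging to the upper
#' class).  The conventional basis is a 20 s sliding window.
#'
#' @param sigma_g Standard deviation of the magnitude in g (>= 0); vectorized.
#' @return Factor with levels Rest, Light, Moderate, Vigorous.
#' @export
classify_motion <- function(sigma_g) {
  if (any(sigma_g < 0)) stop("sigma_g must be non-negative")
  cut(sigma_g, breaks = c(-Inf, 0.1, 0.3, 0.6, Inf), right = FALSE,
      labels = c("Rest", "Light", "Moderate", "Vigorous"))
}

#' Auxiliary motion labels from mean magnitude
#'
#' The auxiliary supervision rule used by the accelerometer stream's motion
#' head: windows are labelled by mean magnitude in m/s^2 with breakpoints
#' 0.2, 1.0 and 3.0 (Rest below 0.2, Vigorous above 3.0).  This coexists with
#' [classify_motion()], which drives reporting; the magnitude rule generates
#' the 4-class auxiliary-task targets.
#'
#' @param mu_ms2 Mean accelerometer magnitude in m/s^2; vectorized.
#' @return Integer class ids 0..3 (Rest, Light, Moderate, Vigorous).
#' @export
motion_aux_label <- function(mu_ms2) {
  if (any(mu_ms2 < 0)) stop("magnitude must be non-negative")
  as.integer(cut(mu_ms2, breaks = c(-Inf, 0.2, 1.0, 3.0, Inf),
                 right = FALSE, labels = FALSE)) - 1L
}
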