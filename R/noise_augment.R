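#' Electrode-motion noise bank
#'
#' Wraps a long single-channel electrode-motion noise sequence for SNR-
#' calibrated mixing.  The sequence is z-scored (zero mean, unit variance) on
#' construction.  The source may be a real noise-stress-test record read with
#' [read_record()] (its ECG channel is treated as noise) or the synthetic
#' surrogate from [synth_em_noise()].
#'
#' @param noise Numeric noise sequence.
#' @param fs Sampling rate in Hz.
#' @param source `"nst_file"` or `"synthetic"`.
#' @return A `noise_bank` object.
#' @export
noise_bank <- function(noise, fs, source = c("synthetic", "nst_file")) {
  source <- match.arg(source)
  noise <- as.numeric(noise)
  if (length(noise) < 2) stop("noise sequence too short")
  noise <- (noise - mean(noise)) / stats::sd(noise)
  structure(list(em_noise = noise, fs = fs, source = source),
            class = "noise_bank")
}

#' Noise scaling factor for a target SNR
#'
#' Computes the amplitude factor `alpha` such that `x + alpha * n` attains
#' the requested power-ratio SNR:
#' `alpha = sqrt( P_signal / (P_noise * 10^(SNR_dB / 10)) )`,
#' with mean-square powers.
#'
#' @param signal Clean signal (must have nonzero power).
#' @param noise Noise segment (must have nonzero power).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return Scalar `alpha`.
#' @export
noise_scale <- function(signal, noise, snr_db) {
  p_sig <- mean(signal^2)
  p_noise <- mean(noise^2)
  if (p_noise <= 0) stop("noise has zero power")
  if (p_sig <= 0) stop("signal has zero power")
  sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
}

#' Mix a signal with bank noise at a target SNR
#'
#' Draws a random contiguous slice from the noise bank (uniform over valid
#' offsets, seeded), scales it with [noise_scale()] computed from the actual
#' slice, and adds it, so the empirical SNR of the mix equals the target up
#' to floating point.  `snr_db = Inf` is the no-noise sentinel and returns
#' the input unchanged.
#'
#' @param signal Clean signal.
#' @param bank A [noise_bank()] at least as long as `signal`.
#' @param snr_db Target SNR in dB (or `Inf`).
#' @param seed Integer seed for the slice draw.
#' @return Noisy signal, same length; attribute `alpha` carries the scale.
#' @export
mix_at_snr <- function(signal, bank, snr_db, seed = 1L) {
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  stopifnot(inherits(bank, "noise_bank"))
  n <- length(signal)
  if (length(bank$em_noise) < n) stop("noise bank shorter than the signal")
  rng <- local_rng(seed)
  off <- rng$sample(length(bank$em_noise) - n + 1L, 1L)
  slice <- bank$em_noise[off:(off + n - 1L)]
  alpha <- noise_scale(signal, slice, snr_db)
  out <- signal + alpha * slice
  attr(out, "alpha") <- alpha
  out
}

#' SNR-coupled synthetic accelerometer segment
#'
#' Generates a tri-axial accelerometer trace as three independent Gaussian
#' processes low-pass filtered at `fc`, then globally rescaled so the
#' root-mean-square magnitude equals the SNR-coupled target
#' `0.4 * 10^(-SNR_dB / d) m/s^2` (`d = 10` by default; `d = 20` selects the
#' amplitude-domain reading of the exponent).  Lower SNR -- heavier ECG
#' corruption -- thus yields proportionally stronger motion, emulating the
#' physical coupling between body movement and electrode artifacts.
#'
#' @param snr_db SNR tag in dB driving the magnitude target.
#' @param duration_s Segment duration in seconds (default 20).
#' @param fs Sampling rate in Hz (default 100).
#' @param fc Low-pass corner in Hz (default 20).
#' @param seed Integer seed.
#' @param exponent_denominator 10 (power-domain, default) or 20.
#' @return 3 x N numeric matrix in m/s^2; attribute `target_rms` carries the
#'   magnitude target.
#' @export
synth_accel <- function(snr_db, duration_s = 20, fs = 100, fc = 20,
                        seed = 1L, exponent_denominator = 10) {
  n <- round(duration_s * fs)
  if (n < 10) stop("segment too short")
  rng <- local_rng(seed)
  a <- matrix(rng$rnorm(3 * n), nrow = 3)
  lp <- signal::butter(4, fc / (fs / 2), type = "low")
  for (i in 1:3) a[i, ] <- as.numeric(signal::filtfilt(lp, a[i, ]))
  target <- 0.4 * 10^(-snr_db / exponent_denominator)
  rms_mag <- sqrt(mean(accel_magnitude(a)^2))
  a <- a * (target / rms_mag)
  attr(a, "target_rms") <- target
  a
}

#' Multi-SNR dataset expansion
#'
#' Expands a set of clean beats by mixing each one at every SNR in `snrs`
#' (default the training grid 24, 12, 6 dB) and pairing it with an
#' SNR-coupled synthetic accelerometer segment at the same level.  Output
#' count is exactly `n_beats * length(snrs)`; labels and source records are
#' preserved.
#'
#' @param beats A `beat_set` (see [extract_beats()]) of clean beats.
#' @param bank A [noise_bank()].
#' @param snrs Numeric SNR grid in dB (default `c(24, 12, 6)`).
#' @param seed Integer seed; each (beat, SNR) pair gets its own derived
#'   stream so augmentation is reproducible beat by beat.
#' @param accel_duration_s,accel_fs Accelerometer segment geometry
#'   (default 20 s at 100 Hz).
#' @return An `augmented_set`: list with `ecg_clean`, `ecg_noisy`
#'   (width x n matrices), `accel` (list of 3 x N matrices), `snr_db`,
#'   `labels`, `source_record`.
#' @export
expand_multisnr <- function(beats, bank, snrs = c(24, 12, 6), seed = 1L,
                            accel_duration_s = 20, accel_fs = 100) {
  stopifnot(inherits(beats, "beat_set"))
  nb <- ncol(beats$windows)
  if (nb == 0) stop("no beats to augment")
  total <- nb * length(snrs)
  width <- nrow(beats$windows)
  ecg_clean <- matrix(0, width, total)
  ecg_noisy <- matrix(0, width, total)
  accel <- vector("list", total)
  snr_tag <- numeric(total)
  labels <- integer(total)
  src <- character(total)
  k <- 0L
  for (s in snrs) {
    for (b in seq_len(nb)) {
      k <- k + 1L
      clean <- beats$windows[, b]
      sd_mix <- derive_seed(seed, sprintf("mix-%d-%g", b, s))
      ecg_clean[, k] <- clean
      ecg_noisy[, k] <- mix_at_snr(clean, bank, s, seed = sd_mix)
      accel[[k]] <- synth_accel(s, duration_s = accel_duration_s,
                                fs = accel_fs,
                                seed = derive_seed(seed, sprintf("acc-%d-%g", b, s)))
      snr_tag[k] <- s
      labels[k] <- if (length(beats$labels)) beats$labels[b] else NA_integer_
      src[k] <- if (length(beats$record_id)) beats$record_id[b] else ""
    }
  }
  structure(list(ecg_clean = ecg_clean, ecg_noisy = ecg_noisy, accel = accel,
                 snr_db = snr_tag, labels = labels, source_record = src,
                 fs = beats$fs),
            class = "augmented_set")
}

#' Empirical SNR of a mixed signal
#'
#' Power-ratio SNR of `noisy` relative to `clean`:
#' `10 log10( P(clean) / P(noisy - clean) )`.
#'
#' @param clean,noisy Equal-length numeric signals.
#' @return SNR in dB (`Inf` when the residual power is zero).
#' @export
empirical_snr <- function(clean, noisy) {
  resid <- noisy - clean
  p_r <- mean(resid^2)
  if (p_r == 0) return(Inf)
  10 * log10(mean(clean^2) / p_r)
}
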