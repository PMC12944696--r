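#' Toy dataset specification
#'
#' Parameters of the synthetic fixture generator.  The defaults give the
#' package's standard toy scale: 10 records of 200 beats with a 32%
#' arrhythmia fraction (the class balance typical of ambulatory arrhythmia
#' archives), heart rates drawn per record from 50--120 bpm.
#'
#' @param n_records,beats_per_record Positive integers.
#' @param arrhythmia_fraction Fraction of beats labelled "V" (in `[0, 1]`).
#' @param heart_rate_bpm Length-2 range of per-record heart rates.
#' @param fs ECG sampling rate in Hz (default 360).
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return A `toy_dataset_spec` list.
#' @export
toy_dataset_spec <- function(n_records = 10L, beats_per_record = 200L,
                             arrhythmia_fraction = 0.32,
                             heart_rate_bpm = c(50, 120), fs = 360,
                             seed = 1L) {
  stopifnot(n_records >= 1, beats_per_record >= 1,
            arrhythmia_fraction >= 0, arrhythmia_fraction <= 1)
  structure(list(n_records = as.integer(n_records),
                 beats_per_record = as.integer(beats_per_record),
                 arrhythmia_fraction = arrhythmia_fraction,
                 heart_rate_bpm = heart_rate_bpm, fs = fs,
                 seed = as.integer(seed)),
            class = "toy_dataset_spec")
}

#' Synthetic parametric ECG beat
#'
#' Generates a one-window ECG beat of one of two morphology families:
#'
#' * class 0 ("N"): P-QRS-T morphology -- a small P bump, a narrow Ricker
#'   (Mexican-hat) QRS whose spectral peak sits near 10 Hz, and a broad
#'   T bump;
#' * class 1 ("V", PVC-like): widened QRS (at least twice the class-0
#'   duration), no P wave, randomized polarity, discordant T.
#'
#' Amplitudes and widths are jittered so the families are separable but
#' overlapping.  The R index lies at the window center, jittered by up to
#' 5 samples.
#'
#' @param class_id 0 or 1.
#' @param fs Sampling rate in Hz (default 360).
#' @param width Window width in samples (default 360).
#' @param seed Integer seed.
#' @return List with `signal` (length `width`), `r_index` (0-based), and the
#'   drawn `qrs_sigma_s`.
#' @export
synth_ecg_beat <- function(class_id, fs = 360, width = 360L, seed = 1L) {
  stopifnot(class_id %in% c(0L, 1L))
  rng <- local_rng(seed)
  t <- (seq_len(width) - 1) / fs
  center <- (width / 2) / fs
  jit <- round(rng$runif(1, -5, 5))
  r_t <- center + jit / fs
  ricker <- function(t, s) (1 - ((t) / s)^2) * exp(-t^2 / (2 * s^2))
  gauss <- function(t, s) exp(-t^2 / (2 * s^2))
  if (class_id == 0L) {
    qrs_s <- 0.0225 * rng$runif(1, 0.9, 1.1)   # spectral peak ~10 Hz
    amp <- rng$runif(1, 0.9, 1.2)
    sig <- amp * ricker(t - r_t, qrs_s) +
      rng$runif(1, 0.08, 0.16) * gauss(t - (r_t - 0.17), 0.025) +  # P
      rng$runif(1, 0.18, 0.30) * gauss(t - (r_t + 0.26), 0.055)    # T
    polarity <- 1
  } else {
    qrs_s <- 0.0225 * rng$runif(1, 2.2, 2.8)   # widened QRS, no P
    amp <- rng$runif(1, 1.0, 1.4)
    polarity <- sign(rng$runif(1) - 0.5)
    sig <- polarity * amp * ricker(t - r_t, qrs_s) -
      polarity * rng$runif(1, 0.15, 0.30) * gauss(t - (r_t + 0.30), 0.06)
  }
  sig <- sig + 0.005 * rng$rnorm(width)        # sensor noise floor
  r_index <- as.integer(width / 2 + jit)
  list(signal = sig, r_index = r_index, qrs_sigma_s = qrs_s,
       polarity = polarity)
}

#' Synthetic annotated records
#'
#' Concatenates generated beats at the requested heart rate with short
#' baseline segments between them, drawing each beat's class Bernoulli
#' (`arrhythmia_fraction`).  Ground-truth R indices are stored both as beat
#' annotations (symbols "N" / "V") and in the `true_r` attribute.
#'
#' @param spec A [toy_dataset_spec()].
#' @return List of [ecg_record()] objects; each carries attribute `true_r`
#'   (0-based ground-truth R indices).
#' @export
synth_record_set <- function(spec) {
  stopifnot(inherits(spec, "toy_dataset_spec"))
  lapply(seq_len(spec$n_records), function(r) {
    rng <- local_rng(derive_seed(spec$seed, sprintf("record-%d", r)))
    hr <- rng$runif(1, spec$heart_rate_bpm[1], spec$heart_rate_bpm[2])
    rr_samp <- round(60 / hr * spec$fs)
    width <- 360L
    n_b <- spec$beats_per_record
    total <- rr_samp * (n_b + 1L) + width
    ecg <- numeric(total)
    r_idx <- integer(n_b)
    syms <- character(n_b)
    for (b in seq_len(n_b)) {
      cls <- as.integer(rng$runif(1) < spec$arrhythmia_fraction)
      beat <- synth_ecg_beat(cls, fs = spec$fs, width = width,
                             seed = derive_seed(spec$seed,
                                                sprintf("beat-%d-%d", r, b)))
      start <- (b - 1L) * rr_samp + round(rr_samp / 2)
      ix <- start + seq_len(width)
      ecg[ix] <- ecg[ix] + beat$signal
      r_idx[b] <- start + beat$r_index          # 0-based
      syms[b] <- if (cls == 1L) "V" else "N"
    }
    # slow respiratory baseline drift
    ecg <- ecg + 0.03 * sin(2 * pi * 0.25 * seq_len(total) / spec$fs +
                              rng$runif(1, 0, 2 * pi))
    rec <- ecg_record(sprintf("toy%03d", r), ecg, spec$fs,
                      annotations = data.frame(sample = r_idx, symbol = syms,
                                               stringsAsFactors = FALSE))
    attr(rec, "true_r") <- r_idx
    rec
  })
}

#' Synthetic electrode-motion noise
#'
#' A surrogate for electrode-motion artifact noise: low-frequency baseline
#' wander (random-phase drift in the 0.1--0.5 Hz band) plus 5--40 Hz
#' band-limited noise modulated by a smooth random burst envelope.  The
#' output is z-scored.
#'
#' @param n_samples Number of samples (>= fs).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric vector, zero mean and unit variance.
#' @export
synth_em_noise <- function(n_samples, fs, seed = 1L) {
  if (n_samples < fs) stop("need at least one second of noise")
  rng <- local_rng(seed)
  t <- seq_len(n_samples) / fs
  wander <- numeric(n_samples)
  for (f in c(0.1, 0.2, 0.35, 0.5))
    wander <- wander + rng$runif(1, 0.5, 1.5) *
      sin(2 * pi * f * t + rng$runif(1, 0, 2 * pi))
  bp <- signal::butter(2, c(5, 40) / (fs / 2), type = "pass")
  bursts <- as.numeric(signal::filtfilt(bp, rng$rnorm(n_samples)))
  env_lp <- signal::butter(2, 0.3 / (fs / 2), type = "low")
  envelope <- as.numeric(signal::filtfilt(env_lp, abs(rng$rnorm(n_samples))))
  envelope <- pmax(envelope - min(envelope), 0)
  envelope <- envelope / max(envelope, 1e-12)
  v <- wander + 3 * envelope * bursts
  (v - mean(v)) / stats::sd(v)
}

#' Write a toy dataset to disk
#'
#' Materializes a [synth_record_set()] in the columnar fixture dialect (or
#' WFDB) so the reading path can be exercised end to end.
#'
#' @param spec A [toy_dataset_spec()].
#' @param dir Output directory.
#' @param format Passed to [write_record()].
#' @return Character vector of record ids written (invisibly).
#' @export
write_toy_dataset <- function(spec, dir, format = "columnar") {
  recs <- synth_record_set(spec)
  for (r in recs) write_record(r, dir, format = format)
  invisible(vapply(recs, function(r) r$record_id, character(1)))
}
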