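test_that("noise scaling attains the requested power-ratio SNR", {
  set.seed(8)
  x <- rnorm(1000); n <- rnorm(1000)
  x <- x / sqrt(mean(x^2)); n <- n / sqrt(mean(n^2))   # equal power
  expect_equal(noise_scale(x, n, 0), 1, tolerance = 1e-12)
  expect_equal(noise_scale(x, n, 20), 0.1, tolerance = 1e-12)
  for (snr in c(24, 6, 0, -6)) {
    alpha <- noise_scale(x, n, snr)
    got <- 10 * log10(mean(x^2) / mean((alpha * n)^2))
    expect_equal(got, snr, tolerance = 0.01)
  }
  expect_error(noise_scale(x, rep(0, 1000), 6), "zero power")
})

test_that("mixing is exact, seeded, and honors the no-noise sentinel", {
  bank <- small_noise_bank()
  beat <- synth_ecg_beat(0L, seed = 3L)$signal
  expect_identical(mix_at_snr(beat, bank, Inf, seed = 1), beat)
  y1 <- mix_at_snr(beat, bank, 6, seed = 5)
  y2 <- mix_at_snr(beat, bank, 6, seed = 5)
  expect_identical(y1, y2)
  expect_equal(empirical_snr(beat, y1), 6, tolerance = 0.1)
  expect_error(mix_at_snr(rnorm(1e6), bank, 6, seed = 1), "shorter")
})

test_that("noise bank is z-scored regardless of source scaling", {
  nb <- noise_bank(50 + 3 * rnorm(5000), 360)
  expect_lt(abs(mean(nb$em_noise)), 1e-10)
  expect_lt(abs(sd(nb$em_noise) - 1), 0.01)
})

test_that("synthetic accelerometer magnitude follows the SNR coupling", {
  a0 <- synth_accel(0, seed = 2)
  expect_equal(sqrt(mean(accel_magnitude(a0)^2)), 0.4, tolerance = 0.004)
  # strictly decreasing RMS magnitude over the evaluation SNR grid
  rms <- vapply(c(24, 18, 12, 6, 0, -6), function(s)
    sqrt(mean(accel_magnitude(synth_accel(s, seed = 11))^2)), numeric(1))
  expect_true(all(diff(rms) > 0))   # grid is descending in SNR
  expect_gt(sqrt(mean(accel_magnitude(synth_accel(-6, seed = 1))^2)),
            sqrt(mean(accel_magnitude(synth_accel(24, seed = 1))^2)))
  # amplitude-domain exponent variant is also monotone but shallower
  r10 <- sqrt(mean(accel_magnitude(synth_accel(12, seed = 4))^2))
  r20 <- sqrt(mean(accel_magnitude(
    synth_accel(12, seed = 4, exponent_denominator = 20))^2))
  expect_lt(r10, r20)
})

test_that("synthetic accelerometer channels are band-limited at 20 Hz", {
  a <- synth_accel(6, seed = 9, duration_s = 20, fs = 100)
  for (i in 1:3) {
    v <- a[i, ] - mean(a[i, ])
    P <- Mod(stats::fft(v))^2
    fr <- (seq_along(v) - 1) / length(v) * 100
    in_band <- fr > 0 & fr < 50
    expect_lt(sum(P[fr > 25 & fr < 50]) / sum(P[in_band]), 0.05)
  }
})

test_that("multi-SNR expansion honors the count contract and preserves labels", {
  bank <- small_noise_bank()
  task <- small_toy_task()
  beats <- task$beats$train
  nb <- min(100L, ncol(beats$windows))
  sub <- structure(list(windows = beats$windows[, 1:nb],
                        r_peaks = beats$r_peaks[1:nb],
                        labels = beats$labels[1:nb],
                        record_id = beats$record_id[1:nb],
                        fs = beats$fs, width = beats$width,
                        dropped_boundary = 0L, dropped_unmatched = 0L),
                   class = "beat_set")
  aug <- expand_multisnr(sub, bank, snrs = c(24, 12, 6), seed = 2,
                         accel_duration_s = 2)
  expect_equal(ncol(aug$ecg_noisy), nb * 3L)
  expect_equal(as.vector(table(aug$labels)), 3L * as.vector(table(sub$labels)))
  # every augmented beat hits its SNR tag within 0.1 dB
  snr_emp <- vapply(seq_len(ncol(aug$ecg_noisy)), function(i)
    empirical_snr(aug$ecg_clean[, i], aug$ecg_noisy[, i]), numeric(1))
  expect_lt(max(abs(snr_emp - aug$snr_db)), 0.1)
  # SNR-coupled motion: each 6 dB sample moves more than its 24 dB sibling
  rms_of <- function(i) sqrt(mean(accel_magnitude(aug$accel[[i]])^2))
  i24 <- which(aug$snr_db == 24)[1:10]
  i6 <- which(aug$snr_db == 6)[1:10]
  expect_true(all(vapply(i6, rms_of, numeric(1)) >
                    vapply(i24, rms_of, numeric(1))))
})
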