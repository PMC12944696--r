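fs <- 360

test_that("band-pass keeps the passband and attenuates out-of-band tones", {
  spec <- filter_spec(0.5, 40, 4, fs)
  t <- seq_len(20 * fs) / fs
  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass_filter(x, spec)
    i <- (5 * fs):(15 * fs)
    max(Mod(stats::fft(y[i]))) / max(Mod(stats::fft(x[i])))
  }
  expect_equal(bandpass_filter(rep(0, 1000), spec), rep(0, 1000))
  expect_lt(abs(gain_at(10) - 1), 0.05)
  expect_lt(20 * log10(gain_at(120)), -40)
  expect_error(filter_spec(0.5, 200, 4, fs), "Nyquist")
  expect_equal(length(bandpass_filter(rnorm(500), spec)), 500)
})

test_that("windowed z-normalization matches direct window statistics", {
  set.seed(9)
  x <- rnorm(6000)
  z <- windowed_znorm(x, fs)
  # interior samples should agree with explicit centered-window stats
  w <- round(10 * fs); if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  for (i in c(2000, 3000, 4000)) {
    win <- x[(i - half):(i + half)]
    expect_equal(z[i], (x[i] - mean(win)) / sd(win), tolerance = 1e-10)
  }
  expect_equal(windowed_znorm(rep(5, 800), fs), rep(0, 800))
  expect_equal(length(windowed_znorm(rnorm(50), fs)), 50)
})

test_that("windowed z-normalization is affine-invariant away from the clamp", {
  set.seed(10)
  x <- rnorm(4000, sd = 2)
  z1 <- windowed_znorm(x, fs)
  z2 <- windowed_znorm(3.7 * x + 11, fs)
  expect_equal(z1, z2, tolerance = 1e-8)
})

test_that("log-power spectrogram has the analytic floor and bin geometry", {
  S0 <- stft_logpower(rep(0, 360), fs)
  expect_true(all(S0$values == -100))
  expect_equal(dim(S0$values), c(2L, 129L))
  S1 <- stft_logpower(rnorm(256), fs)
  expect_equal(nrow(S1$values), 1L)
  expect_error(stft_logpower(rnorm(200), fs), "shorter")
})

test_that("spectrogram localizes an on-bin sinusoid and scales by 20 log10(c)", {
  k0 <- 20
  x <- sin(2 * pi * (k0 * fs / 256) * seq_len(2560) / fs)
  S <- stft_logpower(x, fs)
  interior <- 2:(nrow(S$values) - 1)
  expect_true(all(apply(S$values[interior, ], 1, which.max) == k0 + 1))
  S3 <- stft_logpower(3 * x, fs)
  lift <- S3$values - S$values
  strong <- S$values > -40          # away from the eps floor
  expect_equal(unname(lift[strong]), rep(20 * log10(3), sum(strong)),
               tolerance = 1e-3)
})

test_that("model-input resize matches a scalar bilinear oracle and normalizes", {
  set.seed(3)
  V <- matrix(rnorm(12), 3, 4)
  side <- 16
  out <- spectrogram_to_input(V, side)
  expect_equal(dim(out), c(side, side))
  expect_equal(mean(out), 0, tolerance = 1e-8)
  expect_equal(sd(as.vector(out)), 1, tolerance = 1e-6)
  # undo the z-norm and compare raw resize against the scalar oracle
  raw <- ecgfuse:::bilinear_resize(V, side, side)
  for (i in c(1, 7, 16)) for (j in c(1, 9, 16)) {
    r <- 1 + (i - 1) * (nrow(V) - 1) / (side - 1)
    cc <- 1 + (j - 1) * (ncol(V) - 1) / (side - 1)
    expect_equal(raw[i, j], bilinear_point(V, r, cc), tolerance = 1e-12)
  }
  expect_true(all(spectrogram_to_input(matrix(5, 4, 4), 8) == 0))
})

test_that("QRS detector is perfect on clean fixture records, 40-180 bpm", {
  spec <- filter_spec(fs = fs)
  tol <- round(0.05 * fs)
  for (hr in c(40, 90, 180)) {
    rec <- fixture_record(hr = hr, n_beats = 40, seed = hr)
    truth <- attr(rec, "true_r")
    det <- detect_qrs(bandpass_filter(rec$ecg, spec), fs)
    sens <- mean(vapply(truth, function(r) any(abs(det - r) <= tol),
                        logical(1)))
    ppv <- mean(vapply(det, function(d) any(abs(truth - d) <= tol),
                       logical(1)))
    expect_equal(sens, 1.0)
    expect_equal(ppv, 1.0)
  }
  expect_warning(out <- detect_qrs(rnorm(100), fs), "shorter than 2 s")
  expect_length(out, 0)
})

test_that("HRV statistics match worked examples and a brute-force oracle", {
  # constant RR: all statistics zero
  pk <- seq(0, by = 360, length.out = 10)
  h <- hrv_metrics(pk, fs)
  expect_equal(c(h$sdnn, h$rmssd, h$pnn50), c(0, 0, 0))
  # RR = 800, 860 ms from three peaks
  pk2 <- c(0, 0.8, 1.66) * fs
  h2 <- hrv_metrics(pk2, fs)
  expect_equal(h2$rmssd, 60, tolerance = 1e-9)
  expect_equal(h2$pnn50, 100)
  # SDNN equals the N-1 sample standard deviation of the RR list
  rr <- c(800, 850, 900, 860)
  pk3 <- cumsum(c(0, rr)) / 1000 * fs
  expect_equal(hrv_metrics(pk3, fs)$sdnn, sd(rr), tolerance = 1e-9)
  expect_error(hrv_metrics(c(0, 360), fs), "at least 3")
})

test_that("HRV agrees exactly with the direct-formula oracle on random lists", {
  set.seed(77)
  for (i in 1:1000) {
    n_rr <- sample(3:40, 1)
    rr <- runif(n_rr, 400, 1200)
    pk <- cumsum(c(0, rr)) / 1000 * fs
    h <- hrv_metrics(pk, fs)
    rr_ms <- diff(pk) / fs * 1000
    d <- diff(rr_ms)
    expect_identical(h$sdnn, sd(rr_ms))
    expect_identical(h$rmssd, sqrt(sum(d^2) / (n_rr - 1)))
    expect_identical(h$pnn50, 100 / (n_rr - 1) * sum(abs(d) > 50))
  }
})

test_that("beat extraction drops boundary windows and matches annotations", {
  x <- rnorm(360)
  b <- extract_beats(x, r_peaks = 180L, fs, width = 360L)
  expect_equal(ncol(b$windows), 1L)
  expect_equal(b$windows[, 1], x)          # exact fit
  b2 <- extract_beats(x, r_peaks = 10L, fs, width = 360L)
  expect_equal(ncol(b2$windows), 0L)
  expect_equal(b2$dropped_boundary, 1L)
  # count oracle on a long record: annotations >= width/2 from both ends
  rec <- fixture_record(hr = 80, n_beats = 60, seed = 12)
  lab <- map_labels(rec$annotations, label_scheme("binary"))
  truth <- attr(rec, "true_r")
  b3 <- extract_beats(rec$ecg, truth, fs, width = 360L, labels = lab)
  n_expected <- sum(truth - 180 >= 0 & truth + 180 <= length(rec$ecg))
  expect_equal(ncol(b3$windows), n_expected)
  expect_equal(b3$labels, lab$class_id[truth - 180 >= 0 &
                                         truth + 180 <= length(rec$ecg)])
})
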