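#' Band-pass filter specification
#'
#' Describes a Butterworth band-pass filter realized as cascaded second-order
#' sections.  The default ECG conditioning band is 0.5--40 Hz (order 4); the
#' wider 0.5--50 Hz variant and the accelerometer band 0.1--20 Hz are obtained
#' by changing the cutoffs.
#'
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high < fs/2`.
#' @param order Filter order (of the underlying low-pass prototype).
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec` object holding the cutoffs and the second-order
#'   sections matrix (`sos`, columns b0 b1 b2 a1 a2).
#' @export
filter_spec <- function(f_low = 0.5, f_high = 40, order = 4, fs = 360) {
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high")
  if (f_high >= fs / 2) stop("upper cutoff must be below the Nyquist rate")
  if (order < 1) stop("order must be >= 1")
  bt <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  zpg <- signal::as.Zpg(bt)
  sos <- zpk_to_sos(zpg$zero, zpg$pole, zpg$gain)
  structure(list(f_low = f_low, f_high = f_high, order = order, fs = fs,
                 sos = sos),
            class = "filter_spec")
}

# Pair poles and zeros into biquad sections (poles nearest the unit circle
# first, each matched with the closest remaining zeros); the overall gain is
# folded into the first section.
zpk_to_sos <- function(z, p, k) {
  pair_conj <- function(r) {
    r <- r[order(Im(r) >= 0, Re(r), abs(Im(r)))]
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-10) {       # real root: pair with another real
        j <- which(!used & abs(Im(r)) < 1e-10)
        if (length(j)) { used[j[1]] <- TRUE; pairs <- c(pairs, list(c(r[i], r[j[1]]))) }
        else pairs <- c(pairs, list(r[i]))
      } else {                            # complex: pair with its conjugate
        j <- which(!used & abs(r - Conj(r[i])) < 1e-8)
        if (!length(j)) j <- which(!used)[1]
        used[j[1]] <- TRUE
        pairs <- c(pairs, list(c(r[i], r[j[1]])))
      }
    }
    pairs
  }
  pp <- pair_conj(p)
  zz <- pair_conj(z)
  # order pole pairs by closeness to the unit circle (most selective first)
  pp <- pp[order(vapply(pp, function(q) 1 - max(abs(q)), numeric(1)))]
  sos <- matrix(0, nrow = length(pp), ncol = 5,
                dimnames = list(NULL, c("b0", "b1", "b2", "a1", "a2")))
  for (i in seq_along(pp)) {
    # nearest remaining zero pair
    if (length(zz)) {
      d <- vapply(zz, function(q) min(Mod(q[1] - pp[[i]][1])), numeric(1))
      j <- which.min(d)
      zpair <- zz[[j]]; zz <- zz[-j]
    } else zpair <- complex(0)
    a <- Re(poly_from_roots(pp[[i]]))
    b <- Re(poly_from_roots(zpair))
    b <- c(b, rep(0, 3 - length(b)))
    sos[i, ] <- c(b, a[2], a[3])
  }
  sos[1, 1:3] <- sos[1, 1:3] * Re(k)
  sos
}

poly_from_roots <- function(r) {
  coef <- 1
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the band-pass of a [filter_spec()] forward and backward (zero
#' phase, so QRS timing is preserved), section by section.  Reflection
#' padding of up to one second at each edge limits start-up transients.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= 3 * spec$order) stop("signal too short for the requested order")
  pad <- min(n - 1, round(spec$fs))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  run <- function(v) {
    for (i in seq_len(nrow(spec$sos))) {
      s <- spec$sos[i, ]
      v <- as.numeric(signal::filter(c(s[1], s[2], s[3]), c(1, s[4], s[5]), v))
    }
    v
  }
  y <- rev(run(rev(run(xp))))
  y[(pad + 1):(pad + n)]
}

#' Sliding-window z-normalization
#'
#' Normalizes each sample by the mean and (sample) standard deviation of a
#' centered sliding window, with symmetric padding at the edges and a lower
#' clamp on the standard deviation so flat-line segments map to zero instead
#' of blowing up.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 10).
#' @param sigma_min Lower clamp on the window standard deviation
#'   (default 0.01, in the units of `x`).
#' @return Normalized signal, same length as `x`.
#' @export
windowed_znorm <- function(x, fs, window_s = 10, sigma_min = 0.01) {
  n <- length(x)
  w <- max(2L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L   # odd width so the window is truly centered
  half <- (w - 1L) %/% 2L
  # symmetric (reflection) padding
  left <- x[pmin(n, pmax(1, (half + 1):2))]
  right <- x[pmin(n, pmax(1, (n - 1):(n - half)))]
  if (half > n - 1) {            # signal shorter than half window: reflect cyclically
    idx <- c(rev(seq_len(n))[-1], seq_len(n))
    reflect <- function(k) {
      m <- 2 * (n - 1); if (m == 0) return(rep(1L, k))
      pos <- ((seq_len(k)) - 1) %% m + 1
      ifelse(pos <= n, pos, 2 * n - pos)
    }
    left <- x[rev(reflect(half))]
    right <- x[reflect(half)]
  }
  xp <- c(left, x, right)
  cs <- cumsum(c(0, xp)); cs2 <- cumsum(c(0, xp^2))
  i0 <- seq_len(n); i1 <- i0 + w
  s <- cs[i1] - cs[i0]; s2 <- cs2[i1] - cs2[i0]
  mu <- s / w
  var_ <- pmax(0, (s2 - s^2 / w) / (w - 1))
  sigma <- pmax(sqrt(var_), sigma_min)
  (x - mu) / sigma
}

#' Log-power spectrogram (STFT)
#'
#' Computes the short-time Fourier transform with a Hann window and returns
#' the log-compressed power, `10 log10(|X|^2 + eps)`.
#'
#' @param x Numeric signal (length >= `L`).
#' @param fs Sampling rate in Hz.
#' @param L Window length in samples (default 256).
#' @param H Hop size in samples (default 64, i.e. 75% overlap).
#' @param eps Power floor (default 1e-10, so silence maps to -100 dB).
#' @return An `ecg_spectrogram` with `values` (frames x bins, dB),
#'   `frame_times` (s, window centers), `bin_freqs` (Hz), `L`, `H`, `eps`.
#' @export
stft_logpower <- function(x, fs, L = 256L, H = 64L, eps = 1e-10) {
  n <- length(x)
  if (n < L) stop("signal shorter than one analysis window")
  M <- (n - L) %/% H + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))   # Hann
  frames <- vapply(seq_len(M) - 1L,
                   function(m) x[m * H + seq_len(L)] * w,
                   numeric(L))
  X <- stats::mvfft(frames)[seq_len(L %/% 2 + 1L), , drop = FALSE]
  vals <- t(10 * log10(Mod(X)^2 + eps))
  structure(list(values = vals,
                 frame_times = ((seq_len(M) - 1L) * H + L / 2) / fs,
                 bin_freqs = (0:(L %/% 2)) * fs / L,
                 L = L, H = H, eps = eps, fs = fs),
            class = "ecg_spectrogram")
}

#' Spectrogram to fixed-size model input
#'
#' Bilinearly resizes a log-power spectrogram to `side x side` and applies
#' global z-score normalization (`eps = 1e-8` in the denominator); a constant
#' input therefore maps to all zeros.
#'
#' @param S An `ecg_spectrogram` (or a plain numeric matrix).
#' @param side Output side length (default 224).
#' @return A `side x side` numeric matrix with mean ~0 and sd ~1.
#' @export
spectrogram_to_input <- function(S, side = 224L) {
  V <- if (inherits(S, "ecg_spectrogram")) S$values else as.matrix(S)
  if (!all(is.finite(V))) stop("spectrogram must be finite")
  out <- bilinear_resize(V, side, side)
  mu <- mean(out); sg <- stats::sd(as.vector(out))
  if (!is.finite(sg)) sg <- 0
  (out - mu) / (sg + 1e-8)
}

# Bilinear resampling on the align-corners grid: output point i of n maps to
# source coordinate 1 + (i-1)(m-1)/(n-1).
bilinear_resize <- function(V, rows, cols) {
  interp_w <- function(m, n) {
    if (m == 1) return(matrix(1, nrow = n, ncol = 1))
    src <- 1 + (seq_len(n) - 1) * (m - 1) / (n - 1)
    lo <- pmin(floor(src), m - 1)
    fr <- src - lo
    W <- matrix(0, nrow = n, ncol = m)
    W[cbind(seq_len(n), lo)] <- 1 - fr
    W[cbind(seq_len(n), lo + 1)] <- W[cbind(seq_len(n), lo + 1)] + fr
    W
  }
  Wr <- interp_w(nrow(V), rows)
  Wc <- interp_w(ncol(V), cols)
  Wr %*% V %*% t(Wc)
}

#' QRS detection with adaptive thresholds
#'
#' Pan--Tompkins style detector: five-point derivative, squaring, 150 ms
#' moving-window integration, then adaptive peak classification.  A candidate
#' integration peak `P` is accepted as a signal peak when
#' `P > NPKI + 0.25 (SPKI - NPKI)`; the matching tracker is updated as
#' `0.125 P + 0.875 (previous)`.  A 200 ms refractory period suppresses
#' double detections, a search-back at half threshold recovers beats missed
#' during long RR gaps, and accepted peaks are refined to the local extremum
#' of the (band-passed) input within +/-50 ms.
#'
#' @param x Band-pass filtered ECG.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 0-based R-peak sample indices.  Signals shorter
#'   than 2 s yield `integer(0)` with a warning.
#' @export
detect_qrs <- function(x, fs) {
  n <- length(x)
  if (n < 2 * fs) {
    warning("signal shorter than 2 s; no QRS detection attempted")
    return(integer(0))
  }
  # derivative (five-point), squaring, moving-window integration (150 ms)
  d <- c(0, 0, (2 * x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - 2 * x[1:(n - 4)]) / 8, 0, 0)
  sq <- d^2
  wlen <- max(2L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / wlen, wlen), sides = 1)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  # candidate peaks: local maxima of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(pk)) return(integer(0))
  warm <- seq_len(min(n, 2 * fs))
  spki <- 0.25 * max(mwi[warm])
  npki <- 0.5 * mean(mwi[warm])
  refractory <- round(0.200 * fs)
  half_win <- round(0.050 * fs)
  r_idx <- integer(0)
  last_r <- -Inf
  rr_avg <- NA_real_
  accept <- function(i) {
    lo <- max(1L, i - half_win); hi <- min(n, i + half_win)
    lo - 1L + which.max(abs(x[lo:hi]))
  }
  for (i in pk) {
    p <- mwi[i]
    thr <- npki + 0.25 * (spki - npki)
    if (i - last_r <= refractory) next
    if (p > thr) {
      r <- accept(i)
      if (length(r_idx) && r - r_idx[length(r_idx)] <= refractory) next
      if (length(r_idx)) {
        rr <- r - r_idx[length(r_idx)]
        rr_avg <- if (is.na(rr_avg)) rr else 0.875 * rr_avg + 0.125 * rr
      }
      r_idx <- c(r_idx, r)
      last_r <- i
      spki <- 0.125 * p + 0.875 * spki
    } else {
      npki <- 0.125 * p + 0.875 * npki
      # search-back: if no beat for 1.66x the running RR average, accept the
      # strongest candidate above half threshold
      if (!is.na(rr_avg) && (i - last_r) > 1.66 * rr_avg && p > thr / 2) {
        r <- accept(i)
        if (!length(r_idx) || r - r_idx[length(r_idx)] > refractory) {
          r_idx <- c(r_idx, r)
          last_r <- i
          spki <- 0.125 * p + 0.875 * spki
        }
      }
    }
  }
  as.integer(sort(unique(r_idx)) - 1L)   # 0-based
}

#' Heart-rate-variability statistics
#'
#' Computes SDNN, RMSSD and pNN50 from detected R-peaks.  RR intervals are in
#' milliseconds; both SDNN and RMSSD use the `N - 1` denominator, and
#' `pNN50 = 100/(N-1) * #( |successive difference| > 50 ms )`, where `N` is
#' the number of RR intervals.
#'
#' @param r_peaks Integer sample indices of R-peaks (>= 3).
#' @param fs Sampling rate in Hz.
#' @return An `hrv_stats` list: `sdnn`, `rmssd`, `pnn50` (all ms or percent),
#'   `mean_rr`, `n_intervals`.
#' @export
hrv_metrics <- function(r_peaks, fs) {
  if (length(r_peaks) < 3)
    stop("HRV statistics need at least 3 R-peaks")
  rr <- diff(sort(as.numeric(r_peaks))) / fs * 1000
  n <- length(rr)
  drr <- diff(rr)
  structure(list(sdnn = stats::sd(rr),
                 rmssd = sqrt(sum(drr^2) / (n - 1)),
                 pnn50 = 100 / (n - 1) * sum(abs(drr) > 50),
                 mean_rr = mean(rr),
                 n_intervals = n),
            class = "hrv_stats")
}

#' Extract beat windows centered on R-peaks
#'
#' Cuts fixed-width half-open windows `[r - width/2, r + width/2)` around
#' each R-peak (0-based indices).  Windows that would cross a record boundary
#' are dropped and counted.  When a label table is supplied, each beat takes
#' the class of the nearest annotation within `tol_ms` of its R-peak, and
#' unmatched beats are dropped (and counted).
#'
#' @param x ECG signal the peaks refer to.
#' @param r_peaks Integer 0-based R-peak indices.
#' @param fs Sampling rate in Hz.
#' @param width Window width in samples (default 360).
#' @param labels Optional data frame `sample`, `class_id` from [map_labels()].
#' @param tol_ms Annotation matching tolerance in ms (default 50).
#' @param record_id Source record id carried on each beat.
#' @return A `beat_set`: list with `windows` (width x n matrix), `r_peaks`,
#'   `labels` (integer or NA), `record_id`, `dropped_boundary`,
#'   `dropped_unmatched`.
#' @export
extract_beats <- function(x, r_peaks, fs, width = 360L, labels = NULL,
                          tol_ms = 50, record_id = "") {
  half <- width %/% 2
  n <- length(x)
  r_peaks <- as.integer(r_peaks)
  inside <- r_peaks - half >= 0L & r_peaks - half + width <= n
  dropped_boundary <- sum(!inside)
  keep <- r_peaks[inside]
  lab <- rep(NA_integer_, length(keep))
  dropped_unmatched <- 0L
  if (!is.null(labels) && nrow(labels) > 0 && length(keep)) {
    tol <- tol_ms / 1000 * fs
    for (i in seq_along(keep)) {
      d <- abs(labels$sample - keep[i])
      j <- which.min(d)
      if (d[j] <= tol) lab[i] <- labels$class_id[j]
    }
    dropped_unmatched <- sum(is.na(lab))
    keep <- keep[!is.na(lab)]
    lab <- lab[!is.na(lab)]
  }
  win <- if (length(keep))
    vapply(keep, function(r) x[(r - half + 1L):(r - half + width)],
           numeric(width))
  else matrix(numeric(0), nrow = width, ncol = 0)
  structure(list(windows = win, r_peaks = keep, labels = lab,
                 record_id = rep(record_id, length(keep)),
                 fs = fs, width = width,
                 dropped_boundary = dropped_boundary,
                 dropped_unmatched = dropped_unmatched),
            class = "beat_set")
}
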