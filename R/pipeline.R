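#' Preprocess a record into labelled clean beats
#'
#' The standard conditioning chain: band-pass filter, sliding-window
#' z-normalization, QRS detection, beat-window extraction with labels
#' matched from the record's annotations.
#'
#' @param record An [ecg_record()].
#' @param scheme A [label_scheme()].
#' @param fspec A [filter_spec()] (default: the ECG band at the record rate).
#' @param width Beat window width in samples.
#' @return A `beat_set` (see [extract_beats()]).
#' @export
record_to_beats <- function(record, scheme = label_scheme("binary"),
                            fspec = NULL, width = 360L) {
  fspec <- fspec %||% filter_spec(fs = record$fs_ecg)
  x <- windowed_znorm(bandpass_filter(record$ecg, fspec), record$fs_ecg)
  r <- detect_qrs(x, record$fs_ecg)
  lab <- map_labels(record$annotations, scheme)
  extract_beats(x, r, record$fs_ecg, width = width, labels = lab,
                record_id = record$record_id)
}

#' Beat window to model input
#'
#' Log-power spectrogram of one beat window, resized and normalized for the
#' spectrogram encoder.
#'
#' @param window Numeric beat window.
#' @param fs Sampling rate in Hz.
#' @param side Output side length.
#' @param L,H STFT window and hop (defaults 256 / 64).
#' @return `side x side` matrix.
#' @export
beat_to_input <- function(window, fs, side = 224L, L = 256L, H = 64L) {
  spectrogram_to_input(stft_logpower(window, fs, L = L, H = H), side = side)
}

# merge several beat_sets into one
combine_beats <- function(beat_sets) {
  keep <- Filter(function(b) ncol(b$windows) > 0, beat_sets)
  if (!length(keep)) stop("no beats to combine")
  structure(list(
    windows = do.call(cbind, lapply(keep, `[[`, "windows")),
    r_peaks = unlist(lapply(keep, `[[`, "r_peaks")),
    labels = unlist(lapply(keep, `[[`, "labels")),
    record_id = unlist(lapply(keep, `[[`, "record_id")),
    fs = keep[[1]]$fs, width = keep[[1]]$width,
    dropped_boundary = sum(vapply(keep, `[[`, numeric(1), "dropped_boundary")),
    dropped_unmatched = sum(vapply(keep, `[[`, numeric(1), "dropped_unmatched"))),
    class = "beat_set")
}

#' Augmented samples to a model-ready dataset
#'
#' Converts an `augmented_set` (see [expand_multisnr()]) into a
#' `fusion_dataset`: noisy-beat spectrogram inputs, accelerometer segments
#' (resampled to the model's input length when needed), class labels, and
#' auxiliary motion labels from the mean accelerometer magnitude.
#'
#' @param aug An `augmented_set`.
#' @param config A [model_config()].
#' @param use_clean Use the clean instead of the noisy ECG (for clean
#'   evaluation sets).
#' @return A `fusion_dataset`.
#' @export
augmented_to_dataset <- function(aug, config, use_clean = FALSE) {
  n <- ncol(aug$ecg_noisy)
  src <- if (use_clean) aug$ecg_clean else aug$ecg_noisy
  spec <- vector("list", n); acc <- vector("list", n)
  motion <- integer(n)
  for (i in seq_len(n)) {
    spec[[i]] <- beat_to_input(src[, i], aug$fs, side = config$input_side)
    a <- aug$accel[[i]]
    if (ncol(a) != config$acc_input_len)
      a <- resample_accel(a, config$acc_input_len)
    acc[[i]] <- a
    motion[i] <- motion_aux_label(mean(accel_magnitude(a)))
  }
  make_fusion_dataset(spec, acc, aug$labels, motion_labels = motion,
                      snr_db = aug$snr_db)
}

# block-average (or linear-interpolate) each axis to the target length
resample_accel <- function(a, len) {
  n <- ncol(a)
  if (n == len) return(a)
  if (n %% len == 0) {
    k <- n %/% len
    t(vapply(1:3, function(i) colMeans(matrix(a[i, ], nrow = k)),
             numeric(len)))
  } else {
    idx <- seq(1, n, length.out = len)
    lo <- pmin(floor(idx), n - 1); fr <- idx - lo
    t(vapply(1:3, function(i) a[i, lo] * (1 - fr) + a[i, lo + 1] * fr,
             numeric(len)))
  }
}

#' Build the toy screening task
#'
#' Generates the package's standard CPU-scale experiment: synthetic records,
#' a record-level stratified split, clean beat extraction, multi-SNR
#' augmentation of the training partition (24/12/6 dB), and clean validation
#' and test sets, all converted to model inputs.  Accelerometer segments are
#' generated 2 s long to match the scaled model's input; clean partitions
#' get rest-level (24 dB) accelerometer context.
#'
#' @param spec A [toy_dataset_spec()].
#' @param config A [model_config()] (typically [toy_model_config()]).
#' @param snrs Training SNR grid in dB.
#' @param seed Integer seed for augmentation and splitting.
#' @return List with `train`, `val`, `test` (`fusion_dataset`s), the `split`,
#'   and the clean `beats` per partition.
#' @export
make_toy_task <- function(spec = toy_dataset_spec(),
                          config = toy_model_config(),
                          snrs = c(24, 12, 6), seed = 1L) {
  recs <- synth_record_set(spec)
  scheme <- label_scheme("binary")
  beats <- lapply(recs, record_to_beats, scheme = scheme)
  counts <- data.frame(
    n_normal = vapply(beats, function(b) sum(b$labels == 0L), numeric(1)),
    n_arrhythmia = vapply(beats, function(b) sum(b$labels == 1L), numeric(1)))
  ids <- vapply(recs, function(r) r$record_id, character(1))
  split <- split_records(ids, counts, seed = derive_seed(seed, "split"))
  pick <- function(part_ids) combine_beats(beats[ids %in% part_ids])
  tr_beats <- pick(split$train_ids)
  va_beats <- pick(split$val_ids)
  te_beats <- pick(split$test_ids)
  bank <- noise_bank(synth_em_noise(200000, spec$fs,
                                    seed = derive_seed(seed, "noise")),
                     spec$fs)
  acc_dur <- config$acc_input_len / 100
  aug_tr <- expand_multisnr(tr_beats, bank, snrs = snrs,
                            seed = derive_seed(seed, "augment"),
                            accel_duration_s = acc_dur)
  # clean partitions: no ECG noise; rest-level motion context (24 dB coupling)
  list(train = augmented_to_dataset(aug_tr, config),
       val = augmented_to_dataset(
         clean_augmented(va_beats, acc_dur, derive_seed(seed, "val")), config),
       test = augmented_to_dataset(
         clean_augmented(te_beats, acc_dur, derive_seed(seed, "test")), config),
       split = split,
       beats = list(train = tr_beats, val = va_beats, test = te_beats))
}

#' Gate-diversity ablation at toy scale
#'
#' Trains the scaled-down model on the toy task once per (seed, lambda_gate)
#' pair and reports, per run, the median within-batch gate standard
#' deviation over the last epoch and the final validation accuracy -- the
#' desk-scale version of the gate-collapse ablation.
#'
#' @param task A [make_toy_task()] result.
#' @param seeds Integer vector of training seeds.
#' @param lambdas Gate-penalty weights to compare (default `c(0, 0.1)`).
#' @param epochs Training epochs per run.
#' @param lr Learning rate for the scaled model.
#' @return Data frame with one row per run: `seed`, `lambda`,
#'   `gate_sd_median`, `val_acc`.
#' @export
run_gate_ablation <- function(task, seeds = 1:3, lambdas = c(0, 0.1),
                              epochs = 2L, lr = 1e-3) {
  out <- list()
  for (lam in lambdas) {
    for (sd_ in seeds) {
      model <- fusion_model(toy_model_config(seed = sd_))
      cfg <- train_config(lr = lr, max_epochs = epochs,
                          early_stop_patience = epochs,
                          lambda_gate = lam, seed = sd_)
      fit <- train_fusion(model, task$train, task$val, cfg)
      out[[length(out) + 1L]] <- data.frame(
        seed = sd_, lambda = lam,
        gate_sd_median = stats::median(fit$history$batch_gate_sd),
        val_acc = fit$history$epochs$val_acc[nrow(fit$history$epochs)])
    }
  }
  do.call(rbind, out)
}
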