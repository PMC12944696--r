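#' Training configuration
#'
#' Hyper-parameters of the training loop: Adam at learning rate 1e-4, batch
#' size 16, up to 100 epochs with early stopping on validation accuracy
#' (patience 10), gate-diversity penalty weight `lambda_gate = 0.1` with
#' diversity threshold `tau = 0.3`, and auxiliary motion-loss weight
#' `lambda_motion = 0.3`.
#'
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Epochs without validation-accuracy improvement
#'   before stopping.
#' @param class_weights Cross-entropy class weights (NULL = derive from the
#'   training label distribution via [class_weights_from_distribution()]).
#' @param lambda_gate Gate-diversity penalty weight.
#' @param tau Minimum required within-batch gate standard deviation.
#' @param lambda_motion Auxiliary motion-loss weight.
#' @param seed Integer seed; all training randomness derives from it.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 16L, max_epochs = 100L,
                         early_stop_patience = 10L, class_weights = NULL,
                         lambda_gate = 0.1, tau = 0.3, lambda_motion = 0.3,
                         seed = 1L) {
  stopifnot(lr > 0, batch_size >= 2, max_epochs >= 1,
            early_stop_patience >= 1, lambda_gate >= 0, tau > 0,
            lambda_motion >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 class_weights = class_weights, lambda_gate = lambda_gate,
                 tau = tau, lambda_motion = lambda_motion,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Class weights from a class distribution
#'
#' Majority-normalized inverse-frequency weights: the majority class gets
#' weight 1 and every other class gets `majority fraction / class fraction`.
#' For the 67.9% / 32.1% normal/arrhythmia balance this gives
#' `c(1, 2.12)` (2.115...).
#'
#' @param class_fractions Positive fractions summing to 1.
#' @return Numeric weight vector of the same length.
#' @export
class_weights_from_distribution <- function(class_fractions) {
  if (any(class_fractions <= 0)) stop("every class needs positive frequency")
  if (abs(sum(class_fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  max(class_fractions) / class_fractions
}

#' Gate-diversity hinge loss
#'
#' `max(0, tau - sd(g_ecg)) + max(0, tau - sd(g_acc))` over the within-batch
#' sample standard deviations, so the penalty is active only while the gate
#' values are nearly constant across the batch.  Constant gates give exactly
#' `2 tau`.
#'
#' @param g_ecg,g_acc Gate values across a batch (length >= 2).
#' @param tau Diversity threshold (default 0.3).
#' @return Scalar loss; attribute `grads` holds the list(dg_ecg, dg_acc) of
#'   subgradients.
#' @export
gate_diversity_loss <- function(g_ecg, g_acc, tau = 0.3) {
  n <- length(g_ecg)
  if (n < 2 || length(g_acc) < 2)
    stop("gate diversity needs a batch of at least 2")
  one <- function(g) {
    s <- stats::sd(g)
    if (s >= tau) return(list(loss = 0, dg = numeric(length(g))))
    if (s < 1e-12) return(list(loss = tau, dg = numeric(length(g))))
    list(loss = tau - s, dg = -(g - mean(g)) / ((length(g) - 1) * s))
  }
  a <- one(g_ecg); b <- one(g_acc)
  structure(a$loss + b$loss, grads = list(dg_ecg = a$dg, dg_acc = b$dg))
}

# weighted softmax cross-entropy; labels are 0-based
weighted_ce <- function(logits, labels, weights = NULL) {
  n <- nrow(logits); k <- ncol(logits)
  if (any(labels < 0 | labels >= k)) stop("label outside class range")
  w <- weights %||% rep(1, k)
  p <- softmax_rows(logits)
  wi <- w[labels + 1L]
  pick <- cbind(seq_len(n), labels + 1L)
  loss <- sum(wi * -log(pmax(p[pick], 1e-12))) / sum(wi)
  dz <- p
  dz[pick] <- dz[pick] - 1
  dz <- dz * (wi / sum(wi))
  list(loss = loss, dlogits = dz)
}

#' Combined training objective
#'
#' Weighted cross-entropy on the class logits, plus `lambda_gate` times the
#' gate-diversity hinge, plus `lambda_motion` times an (unweighted)
#' cross-entropy on the auxiliary motion logits when motion labels are
#' supplied.  Gradients for all three heads are returned for the training
#' loop.
#'
#' @param logits B x C class logits.
#' @param labels 0-based class labels.
#' @param g_ecg,g_acc Gate values over the batch.
#' @param motion_logits,motion_labels Optional auxiliary head (B x 4 /
#'   0-based labels).
#' @param cfg A [train_config()].
#' @return List with `total`, `ce`, `gate`, `motion` and the gradient list
#'   `grads` (`dlogits`, `dg_ecg`, `dg_acc`, `dmotion`).
#' @export
total_loss <- function(logits, labels, g_ecg, g_acc, motion_logits = NULL,
                       motion_labels = NULL, cfg = train_config()) {
  ce <- weighted_ce(logits, labels, cfg$class_weights)
  gl <- if (cfg$lambda_gate > 0) gate_diversity_loss(g_ecg, g_acc, cfg$tau)
  else structure(0, grads = list(dg_ecg = numeric(length(g_ecg)),
                                 dg_acc = numeric(length(g_acc))))
  use_motion <- !is.null(motion_logits) && !is.null(motion_labels) &&
    cfg$lambda_motion > 0
  ml <- if (use_motion) weighted_ce(motion_logits, motion_labels) else NULL
  total <- ce$loss + cfg$lambda_gate * as.numeric(gl) +
    if (use_motion) cfg$lambda_motion * ml$loss else 0
  gg <- attr(gl, "grads")
  list(total = total, ce = ce$loss, gate = as.numeric(gl),
       motion = if (use_motion) ml$loss else 0,
       grads = list(dlogits = ce$dlogits,
                    dg_ecg = cfg$lambda_gate * gg$dg_ecg,
                    dg_acc = cfg$lambda_gate * gg$dg_acc,
                    dmotion = if (use_motion) cfg$lambda_motion * ml$dlogits
                    else NULL))
}

#' Assemble a model-ready dataset
#'
#' Bundles per-sample model inputs: normalized square spectrograms, 3 x L
#' accelerometer segments, class labels, and optional motion labels and SNR
#' tags.
#'
#' @param spec_inputs List of side x side matrices (see
#'   [spectrogram_to_input()]).
#' @param acc_inputs List of 3 x L matrices.
#' @param labels 0-based integer class labels.
#' @param motion_labels Optional 0-based motion class labels.
#' @param snr_db Optional per-sample SNR tags.
#' @return A `fusion_dataset` list with element `n`.
#' @export
make_fusion_dataset <- function(spec_inputs, acc_inputs, labels,
                                motion_labels = NULL, snr_db = NULL) {
  n <- length(spec_inputs)
  stopifnot(length(acc_inputs) == n, length(labels) == n)
  structure(list(spec = spec_inputs, acc = acc_inputs,
                 labels = as.integer(labels),
                 motion_labels = if (!is.null(motion_labels))
                   as.integer(motion_labels),
                 snr_db = snr_db, n = n),
            class = "fusion_dataset")
}

dataset_batch <- function(data, idx, config) {
  list(spec = as_spec_batch(data$spec[idx], config$input_side),
       acc = as_acc_batch(data$acc[idx], config$acc_input_len),
       labels = data$labels[idx],
       motion_labels = if (!is.null(data$motion_labels))
         data$motion_labels[idx])
}

#' Train the fusion model
#'
#' Mini-batch Adam training with per-epoch validation, early stopping on
#' validation accuracy, and best-weight restoration.  All randomness
#' (shuffling; dropout was seeded at model construction) derives from
#' `cfg$seed`.  Batches of size 1 are skipped (the within-batch gate standard
#' deviation is undefined there).
#'
#' @param model A [fusion_model()].
#' @param train_data,val_data `fusion_dataset`s; validation is conventionally
#'   clean (un-augmented) data.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained `model` and `history` (a `train_history`:
#'   per-epoch data frame plus `stopped_epoch`, `best_epoch`,
#'   `batch_gate_sd` of the last epoch).
#' @export
train_fusion <- function(model, train_data, val_data = NULL,
                         cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(train_data, "fusion_dataset"))
  if (train_data$n == 0) stop("empty training dataset")
  if (is.null(cfg$class_weights)) {
    fr <- as.vector(table(factor(train_data$labels,
                                 levels = 0:(model$config$n_classes - 1L))))
    cfg$class_weights <- class_weights_from_distribution(fr / sum(fr))
  }
  opt <- adam_optimizer(model$params(), lr = cfg$lr)
  rng <- local_rng(derive_seed(cfg$seed, "shuffle"))
  hist <- list()
  best_acc <- -Inf; best_state <- NULL; best_epoch <- 0L; wait <- 0L
  last_epoch_gate_sd <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- rng$sample(train_data$n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_n <- 0; ep_correct <- 0
    gate_means <- c(0, 0); gate_sds <- numeric(0)
    for (ix in batches) {
      if (length(ix) < 2) next
      ba <- dataset_batch(train_data, ix, model$config)
      out <- model_forward(model, ba$spec, ba$acc, train = TRUE)
      lo <- total_loss(out$logits, ba$labels, out$g_ecg, out$g_acc,
                       out$motion_logits, ba$motion_labels, cfg)
      zero_grads(model$params())
      model_backward(model, lo$grads$dlogits, lo$grads$dmotion,
                     lo$grads$dg_ecg, lo$grads$dg_acc)
      opt$step()
      ep_loss <- ep_loss + lo$total * length(ix)
      ep_n <- ep_n + length(ix)
      ep_correct <- ep_correct +
        sum(max.col(out$probs, ties.method = "first") - 1L == ba$labels)
      gate_means <- gate_means + c(mean(out$g_ecg), mean(out$g_acc)) * length(ix)
      gate_sds <- c(gate_sds,
                    (stats::sd(out$g_ecg) + stats::sd(out$g_acc)) / 2)
    }
    train_loss <- ep_loss / ep_n
    train_acc <- ep_correct / ep_n
    if (!is.null(val_data) && val_data$n > 0) {
      pv <- predict_fusion(model, val_data,
                           batch_size = max(cfg$batch_size, 16L))
      val_acc <- mean(pv$prediction == val_data$labels)
    } else val_acc <- train_acc
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, train_acc = train_acc,
      val_acc = val_acc,
      gate_mean_ecg = gate_means[1] / ep_n, gate_mean_acc = gate_means[2] / ep_n,
      gate_sd_median = stats::median(gate_sds))
    last_epoch_gate_sd <- gate_sds
    if (verbose)
      message(sprintf("epoch %d: loss %.4f train %.3f val %.3f gate-sd %.3f",
                      epoch, train_loss, train_acc, val_acc,
                      stats::median(gate_sds)))
    if (val_acc > best_acc + 1e-12) {
      best_acc <- val_acc; best_epoch <- epoch
      best_state <- model_state(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(best_state)) load_model_state(model, best_state)
  history <- structure(list(epochs = do.call(rbind, hist),
                            stopped_epoch = epoch, best_epoch = best_epoch,
                            best_val_acc = best_acc,
                            batch_gate_sd = last_epoch_gate_sd),
                       class = "train_history")
  list(model = model, history = history)
}
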