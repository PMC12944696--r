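#' Dual-stream model configuration
#'
#' Architecture hyper-parameters of the fusion classifier.  The defaults are
#' the full-size layout: an 18-layer residual encoder over 224 x 224
#' single-channel spectrograms (stages 64/128/256/512, giving a
#' 512-dimensional ECG feature), a CNN-BiLSTM accelerometer encoder over
#' 3 x 2000 segments (conv kernels 25/25/9 with channels 32/64/128, two
#' BiLSTM layers with 64 hidden units per direction, giving a
#' 128-dimensional motion feature), scalar attention gates per modality, and
#' a 640 -> 256 -> n_classes head with dropout 0.5.  The five-class variant
#' inserts an extra 256 -> 128 layer with dropout 0.3 before the output.
#'
#' @param n_classes 2 (binary screening) or 5 (diagnostic stage).
#' @param input_side Spectrogram input side length.
#' @param stem_channels,stage_channels Residual encoder widths.
#' @param acc_input_len Accelerometer samples per segment (3 channels).
#' @param acc_channels,acc_kernels Accelerometer conv layer widths/kernels.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param head_hidden,head_hidden2 Classification head widths.
#' @param motion_classes Auxiliary motion-head classes (4).
#' @param dropout Head dropout probability.
#' @param seed Initialization seed.
#' @return A `model_config` list; `ecg_feature_dim`, `acc_feature_dim` and
#'   `fused_dim` are derived fields.
#' @export
model_config <- function(n_classes = 2L, input_side = 224L,
                         stem_channels = 64L,
                         stage_channels = c(64L, 128L, 256L, 512L),
                         acc_input_len = 2000L,
                         acc_channels = c(32L, 64L, 128L),
                         acc_kernels = c(25L, 25L, 9L),
                         lstm_hidden = 64L, head_hidden = 256L,
                         head_hidden2 = 128L, motion_classes = 4L,
                         dropout = 0.5, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes), input_side = as.integer(input_side),
              stem_channels = as.integer(stem_channels),
              stage_channels = as.integer(stage_channels),
              acc_input_len = as.integer(acc_input_len),
              acc_channels = as.integer(acc_channels),
              acc_kernels = as.integer(acc_kernels),
              lstm_hidden = as.integer(lstm_hidden),
              head_hidden = as.integer(head_hidden),
              head_hidden2 = as.integer(head_hidden2),
              motion_classes = as.integer(motion_classes),
              dropout = dropout, seed = as.integer(seed))
  cfg$ecg_feature_dim <- cfg$stage_channels[length(cfg$stage_channels)]
  cfg$acc_feature_dim <- 2L * cfg$lstm_hidden
  cfg$fused_dim <- cfg$ecg_feature_dim + cfg$acc_feature_dim
  structure(cfg, class = "model_config")
}

#' Scaled-down configuration of the same topology
#'
#' The package's demonstration scale for CPU training: 32 x 32 spectrogram
#' input with stage widths 8/16/32/64, 3 x 200 accelerometer input with conv
#' channels 8/16/32 and 8 hidden LSTM units per direction (so an 80-dim
#' fused feature).  Every structural element of the full model is retained.
#'
#' @param n_classes,seed See [model_config()].
#' @return A `model_config`.
#' @export
toy_model_config <- function(n_classes = 2L, seed = 1L) {
  model_config(n_classes = n_classes, input_side = 32L, stem_channels = 8L,
               stage_channels = c(8L, 16L, 32L, 64L), acc_input_len = 200L,
               acc_channels = c(8L, 16L, 32L), acc_kernels = c(25L, 25L, 9L),
               lstm_hidden = 8L, head_hidden = 32L, head_hidden2 = 16L,
               seed = seed)
}

# residual block: two 3x3 conv+BN, identity or 1x1-projection skip
res_block <- function(rng, in_ch, out_ch, stride) {
  bl <- new.env()
  bl$conv1 <- layer_conv2d(rng, in_ch, out_ch, 3L, stride = stride, bias = FALSE)
  bl$bn1 <- layer_bn2d(out_ch)
  bl$relu1 <- layer_relu()
  bl$conv2 <- layer_conv2d(rng, out_ch, out_ch, 3L, stride = 1L, bias = FALSE)
  bl$bn2 <- layer_bn2d(out_ch)
  bl$relu_out <- layer_relu()
  bl$project <- stride != 1L || in_ch != out_ch
  if (bl$project) {
    bl$conv_p <- layer_conv2d(rng, in_ch, out_ch, 1L, stride = stride,
                              pad_h = 0L, pad_w = 0L, bias = FALSE)
    bl$bn_p <- layer_bn2d(out_ch)
  }
  bl$forward <- function(x, train = TRUE) {
    f <- bl$bn2$forward(bl$conv2$forward(
      bl$relu1$forward(bl$bn1$forward(bl$conv1$forward(x, train), train)),
      train), train)
    s <- if (bl$project) bl$bn_p$forward(bl$conv_p$forward(x, train), train) else x
    bl$relu_out$forward(f + s)
  }
  bl$backward <- function(dout) {
    dsum <- bl$relu_out$backward(dout)
    dx_f <- bl$conv1$backward(bl$bn1$backward(bl$relu1$backward(
      bl$conv2$backward(bl$bn2$backward(dsum)))))
    dx_s <- if (bl$project) bl$conv_p$backward(bl$bn_p$backward(dsum)) else dsum
    dx_f + dx_s
  }
  bl$params <- function() {
    c(bl$conv1$params(), bl$bn1$params(), bl$conv2$params(), bl$bn2$params(),
      if (bl$project) c(bl$conv_p$params(), bl$bn_p$params()))
  }
  bl
}

#' Build the dual-stream fusion model
#'
#' Constructs the spectrogram encoder (7x7 stride-2 stem, 3x3 stride-2 max
#' pool, four residual stages of two blocks each, global average pooling),
#' the accelerometer encoder (three conv1d + max-pool stages, two BiLSTM
#' layers, final-state aggregation, auxiliary motion head), the attention
#' fusion (per-modality batch norm, scalar sigmoid gates from zero-initialized
#' linear maps -- so gates start exactly at 0.5 -- element-wise scaling and
#' concatenation), and the classification head.  All weight initialization is
#' a pure function of `config$seed`.
#'
#' @param config A [model_config()].
#' @return A `fusion_model` environment.
#' @export
fusion_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  m <- new.env()
  m$config <- config
  rng <- local_rng(derive_seed(config$seed, "init"))
  sc <- config$stage_channels
  m$stem <- layer_conv2d(rng, 1L, config$stem_channels, 7L, stride = 2L,
                         pad_h = 3L, pad_w = 3L, bias = FALSE)
  m$stem_bn <- layer_bn2d(config$stem_channels)
  m$stem_relu <- layer_relu()
  m$stem_pool <- layer_maxpool2d(3L, 3L, 2L, 1L, 1L)
  blocks <- list()
  in_ch <- config$stem_channels
  for (i in seq_along(sc)) {
    stride <- if (i == 1L) 1L else 2L
    blocks <- c(blocks, list(res_block(rng, in_ch, sc[i], stride),
                             res_block(rng, sc[i], sc[i], 1L)))
    in_ch <- sc[i]
  }
  m$blocks <- blocks
  m$gap <- layer_global_avgpool()

  ac <- config$acc_channels; ak <- config$acc_kernels
  m$acc_convs <- list(); m$acc_relus <- list(); m$acc_pools <- list()
  in_c <- 3L
  for (i in seq_along(ac)) {
    m$acc_convs[[i]] <- layer_conv2d(rng, in_c, ac[i], ak[i], kw = 1L,
                                     pad_h = (ak[i] - 1L) %/% 2L, pad_w = 0L)
    m$acc_relus[[i]] <- layer_relu()
    m$acc_pools[[i]] <- layer_maxpool2d(2L, 1L, 2L)
    in_c <- ac[i]
  }
  H <- config$lstm_hidden
  m$lstm1 <- layer_bilstm(rng, in_c, H)
  m$lstm2 <- layer_bilstm(rng, 2L * H, H)
  m$motion_head <- layer_dense(rng, config$acc_feature_dim,
                               config$motion_classes)

  m$bn_ecg <- layer_bn1d(config$ecg_feature_dim)
  m$bn_acc <- layer_bn1d(config$acc_feature_dim)
  m$gate_ecg <- layer_dense(rng, config$ecg_feature_dim, 1L, zero_init = TRUE)
  m$gate_acc <- layer_dense(rng, config$acc_feature_dim, 1L, zero_init = TRUE)

  m$drop_rng <- local_rng(derive_seed(config$seed, "dropout"))
  m$fc1 <- layer_dense(rng, config$fused_dim, config$head_hidden)
  m$fc1_relu <- layer_relu()
  m$drop1 <- layer_dropout(config$dropout, m$drop_rng)
  if (config$n_classes >= 5L) {
    m$fc2 <- layer_dense(rng, config$head_hidden, config$head_hidden2)
    m$fc2_relu <- layer_relu()
    m$drop2 <- layer_dropout(0.3, m$drop_rng)
    m$fc_out <- layer_dense(rng, config$head_hidden2, config$n_classes)
  } else {
    m$fc_out <- layer_dense(rng, config$head_hidden, config$n_classes)
  }

  m$ecg_modules <- function() c(list(m$stem, m$stem_bn), m$blocks)
  m$all_modules <- function() {
    c(list(m$stem, m$stem_bn), m$blocks,
      m$acc_convs, list(m$lstm1, m$lstm2, m$motion_head,
                        m$bn_ecg, m$bn_acc, m$gate_ecg, m$gate_acc, m$fc1),
      if (config$n_classes >= 5L) list(m$fc2), list(m$fc_out))
  }
  m$params <- function() unlist(lapply(m$all_modules(),
                                       function(mod) mod$params()),
                                recursive = FALSE)
  class(m) <- c("fusion_model", "environment")
  m
}

# ECG branch forward/backward on a (side, side, 1, B) array
ecg_branch_forward <- function(m, x, train) {
  h <- m$stem_pool$forward(m$stem_relu$forward(
    m$stem_bn$forward(m$stem$forward(x, train), train)), train)
  for (bl in m$blocks) h <- bl$forward(h, train)
  m$gap$forward(h)
}

ecg_branch_backward <- function(m, dfe) {
  dh <- m$gap$backward(dfe)
  for (bl in rev(m$blocks)) dh <- bl$backward(dh)
  m$stem$backward(m$stem_bn$backward(m$stem_relu$backward(
    m$stem_pool$backward(dh))))
}

# Accelerometer branch on a (L, 1, 3, B) array; returns f_acc and motion
# logits plus the shapes needed for backward.
acc_branch_forward <- function(m, x, train) {
  h <- x
  for (i in seq_along(m$acc_convs))
    h <- m$acc_pools[[i]]$forward(m$acc_relus[[i]]$forward(
      m$acc_convs[[i]]$forward(h, train)), train)
  d <- dim(h)                              # (T, 1, C, B)
  seqin <- aperm(array(h, dim = d[c(1, 3, 4)]), c(1, 3, 2))  # (T, B, C)
  o1 <- m$lstm1$forward(seqin, train)
  o2 <- m$lstm2$forward(o1, train)
  T_ <- dim(o2)[1]; H <- m$config$lstm_hidden; B <- dim(o2)[2]
  f_acc <- cbind(matrix(o2[T_, , seq_len(H)], nrow = B),
                 matrix(o2[1L, , H + seq_len(H)], nrow = B))
  m$acc_cache <- list(conv_dim = d, T_ = T_, B = B)
  list(f_acc = f_acc, motion_logits = m$motion_head$forward(f_acc, train))
}

acc_branch_backward <- function(m, df_acc, dmotion = NULL) {
  if (!is.null(dmotion)) df_acc <- df_acc + m$motion_head$backward(dmotion)
  ca <- m$acc_cache
  H <- m$config$lstm_hidden
  do2 <- array(0, dim = c(ca$T_, ca$B, 2L * H))
  do2[ca$T_, , seq_len(H)] <- df_acc[, seq_len(H)]
  do2[1L, , H + seq_len(H)] <- df_acc[, H + seq_len(H)]
  dseq <- m$lstm1$backward(m$lstm2$backward(do2))
  dh <- aperm(dseq, c(1, 3, 2))            # (T, C, B)
  dim(dh) <- ca$conv_dim
  for (i in rev(seq_along(m$acc_convs)))
    dh <- m$acc_convs[[i]]$backward(m$acc_relus[[i]]$backward(
      m$acc_pools[[i]]$backward(dh)))
  dh
}

# Full forward pass.  spec: (side, side, 1, B); acc: (L, 1, 3, B).
model_forward <- function(m, spec, acc, train = FALSE) {
  f_ecg <- ecg_branch_forward(m, spec, train)
  ab <- acc_branch_forward(m, acc, train)
  f_acc <- ab$f_acc
  fe_n <- m$bn_ecg$forward(f_ecg, train)
  fa_n <- m$bn_acc$forward(f_acc, train)
  pre_e <- m$gate_ecg$forward(fe_n, train)
  pre_a <- m$gate_acc$forward(fa_n, train)
  g_e <- sigmoid(as.vector(pre_e))
  g_a <- sigmoid(as.vector(pre_a))
  fused <- cbind(fe_n * g_e, fa_n * g_a)
  h1 <- m$drop1$forward(m$fc1_relu$forward(m$fc1$forward(fused, train)), train)
  logits <- if (m$config$n_classes >= 5L) {
    h2 <- m$drop2$forward(m$fc2_relu$forward(m$fc2$forward(h1, train)), train)
    m$fc_out$forward(h2, train)
  } else m$fc_out$forward(h1, train)
  probs <- softmax_rows(logits)
  m$fwd_cache <- list(fe_n = fe_n, fa_n = fa_n, g_e = g_e, g_a = g_a)
  list(logits = logits, probs = probs, motion_logits = ab$motion_logits,
       g_ecg = g_e, g_acc = g_a, f_ecg = f_ecg, f_acc = f_acc, fused = fused)
}

# Backward from gradients on logits, motion logits, and (optionally) the
# gate values themselves (the gate-diversity penalty attacks gates directly).
model_backward <- function(m, dlogits, dmotion = NULL, dg_ecg = NULL,
                           dg_acc = NULL) {
  ca <- m$fwd_cache
  dh <- if (m$config$n_classes >= 5L) {
    dh2 <- m$fc_out$backward(dlogits)
    m$fc2$backward(m$fc2_relu$backward(m$drop2$backward(dh2)))
  } else m$fc_out$backward(dlogits)
  dfused <- m$fc1$backward(m$fc1_relu$backward(m$drop1$backward(dh)))
  de <- ncol(ca$fe_n)
  dfe_part <- dfused[, seq_len(de), drop = FALSE]
  dfa_part <- dfused[, de + seq_len(ncol(ca$fa_n)), drop = FALSE]
  dg_e <- rowSums(dfe_part * ca$fe_n)
  dg_a <- rowSums(dfa_part * ca$fa_n)
  if (!is.null(dg_ecg)) dg_e <- dg_e + dg_ecg
  if (!is.null(dg_acc)) dg_a <- dg_a + dg_acc
  dpre_e <- dg_e * ca$g_e * (1 - ca$g_e)
  dpre_a <- dg_a * ca$g_a * (1 - ca$g_a)
  dfe_n <- dfe_part * ca$g_e + m$gate_ecg$backward(matrix(dpre_e, ncol = 1))
  dfa_n <- dfa_part * ca$g_a + m$gate_acc$backward(matrix(dpre_a, ncol = 1))
  df_ecg <- m$bn_ecg$backward(dfe_n)
  df_acc <- m$bn_acc$backward(dfa_n)
  ecg_branch_backward(m, df_ecg)
  acc_branch_backward(m, df_acc, dmotion)
  invisible(NULL)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Encode a spectrogram batch to ECG features
#'
#' Runs the residual spectrogram encoder in evaluation mode.
#'
#' @param model A [fusion_model()].
#' @param x A `side x side` matrix or a `(side, side, 1, B)` array.
#' @return B x ecg_feature_dim matrix.
#' @export
ecg_encode <- function(model, x) {
  x <- as_spec_batch(x, model$config$input_side)
  ecg_branch_forward(model, x, train = FALSE)
}

#' Encode an accelerometer batch to motion features
#'
#' Runs the CNN-BiLSTM encoder in evaluation mode.
#'
#' @param model A [fusion_model()].
#' @param a A 3 x L matrix or a list of them.
#' @return List with `f_acc` (B x acc_feature_dim) and `motion_logits`
#'   (B x 4).
#' @export
acc_encode <- function(model, a) {
  x <- as_acc_batch(a, model$config$acc_input_len)
  acc_branch_forward(model, x, train = FALSE)
}

#' Attention-gated fusion of precomputed features
#'
#' Batch-normalizes each modality (inference statistics), computes the scalar
#' sigmoid gates, and returns the gated concatenation together with a gate
#' report.  `force_gates` overrides the computed gates (useful for probing
#' the fusion identity/null behavior).
#'
#' @param model A [fusion_model()].
#' @param f_ecg,f_acc Feature matrices (B x dim).
#' @param force_gates Optional list(g_ecg =, g_acc =) of scalars or vectors.
#' @return List with `fused` (B x fused_dim) and `gates` (a `gate_report`:
#'   g_ecg, g_acc, batch_mean, batch_sd).
#' @export
attention_fuse <- function(model, f_ecg, f_acc, force_gates = NULL) {
  fe_n <- model$bn_ecg$forward(f_ecg, train = FALSE)
  fa_n <- model$bn_acc$forward(f_acc, train = FALSE)
  g_e <- sigmoid(as.vector(model$gate_ecg$forward(fe_n, train = FALSE)))
  g_a <- sigmoid(as.vector(model$gate_acc$forward(fa_n, train = FALSE)))
  if (!is.null(force_gates)) {
    g_e <- rep(force_gates$g_ecg, length.out = nrow(f_ecg))
    g_a <- rep(force_gates$g_acc, length.out = nrow(f_acc))
  }
  list(fused = cbind(fe_n * g_e, fa_n * g_a),
       gates = gate_report(g_e, g_a))
}

#' @rdname attention_fuse
#' @param g_ecg,g_acc Gate value vectors in `[0, 1]`.
#' @export
gate_report <- function(g_ecg, g_acc) {
  structure(list(g_ecg = g_ecg, g_acc = g_acc,
                 batch_mean = c(g_ecg = mean(g_ecg), g_acc = mean(g_acc)),
                 batch_sd = c(g_ecg = if (length(g_ecg) > 1) stats::sd(g_ecg) else 0,
                              g_acc = if (length(g_acc) > 1) stats::sd(g_acc) else 0)),
            class = "gate_report")
}

#' Classify a fused feature batch
#'
#' Runs the classification head in evaluation mode (dropout inactive).
#'
#' @param model A [fusion_model()].
#' @param fused B x fused_dim matrix.
#' @return List with `logits`, `probs` (rows on the simplex), `prediction`
#'   (0-based argmax ids).
#' @export
classify_fused <- function(model, fused) {
  h1 <- model$fc1_relu$forward(model$fc1$forward(fused, train = FALSE))
  logits <- if (model$config$n_classes >= 5L) {
    h2 <- model$fc2_relu$forward(model$fc2$forward(h1, train = FALSE))
    model$fc_out$forward(h2, train = FALSE)
  } else model$fc_out$forward(h1, train = FALSE)
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs,
       prediction = max.col(probs, ties.method = "first") - 1L)
}

#' Post-hoc refinement with temperature scaling and an activity prior
#'
#' Divides the (implied) logits by a temperature, re-normalizes, multiplies
#' element-wise by an activity-conditioned class prior and renormalizes.
#' With a uniform prior and `temperature = 1` this is the identity.  The
#' refinement ships disabled by default because no published prior values
#' accompany the model; it is exposed as a configurable post-hoc step.
#'
#' @param probs Matrix (B x C) or vector of class probabilities.
#' @param activity_prior Prior class-probability vector (or uniform).
#' @param temperature Positive scalar (default 1.5).
#' @return Refined probabilities with the same shape as `probs`.
#' @export
bayesian_refine <- function(probs, activity_prior = NULL, temperature = 1.5) {
  vec <- is.null(dim(probs))
  p <- if (vec) matrix(probs, nrow = 1) else as.matrix(probs)
  k <- ncol(p)
  prior <- activity_prior %||% rep(1 / k, k)
  if (length(prior) != k) stop("prior length must match the class count")
  if (all(prior <= 0)) stop("prior must have mass on at least one class")
  if (temperature <= 0) stop("temperature must be positive")
  pt <- p^(1 / temperature)                 # softmax(log p / T)
  pt <- pt / rowSums(pt)
  out <- sweep(pt, 2, prior, `*`)
  out <- out / rowSums(out)
  if (vec) as.vector(out) else out
}

#' Forward pass over a dataset in evaluation mode
#'
#' @param model A [fusion_model()].
#' @param data A `fusion_dataset` (see [make_fusion_dataset()]).
#' @param batch_size Evaluation batch size.
#' @return List with `probs`, `prediction`, `g_ecg`, `g_acc`,
#'   `motion_pred`.
#' @export
predict_fusion <- function(model, data, batch_size = 32L) {
  n <- data$n
  probs <- NULL; ge <- numeric(0); ga <- numeric(0); mp <- integer(0)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    ba <- dataset_batch(data, ix, model$config)
    out <- model_forward(model, ba$spec, ba$acc, train = FALSE)
    probs <- rbind(probs, out$probs)
    ge <- c(ge, out$g_ecg); ga <- c(ga, out$g_acc)
    mp <- c(mp, max.col(out$motion_logits, ties.method = "first") - 1L)
  }
  list(probs = probs,
       prediction = max.col(probs, ties.method = "first") - 1L,
       g_ecg = ge, g_acc = ga, motion_pred = mp)
}

#' Number of trainable parameters
#'
#' @param model A [fusion_model()].
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params(), function(p) length(p$value), numeric(1)))
}

#' Extract / restore model weights
#'
#' `model_state` captures all parameters and batch-norm running statistics as
#' a plain list (suitable for `saveRDS`); `load_model_state` writes them back
#' into a model built from the same configuration.
#'
#' @param model A [fusion_model()].
#' @return For `model_state`, a list with `config`, `values`, `running`.
#' @export
model_state <- function(model) {
  bn_mods <- Filter(function(mod) !is.null(mod$run_mean), model$all_modules())
  list(config = model$config,
       values = lapply(model$params(), function(p) p$value),
       running = lapply(bn_mods, function(b) list(mean = b$run_mean,
                                                  var = b$run_var)))
}

#' @rdname model_state
#' @param state A list produced by `model_state`.
#' @export
load_model_state <- function(model, state) {
  ps <- model$params()
  stopifnot(length(ps) == length(state$values))
  for (i in seq_along(ps)) ps[[i]]$value <- state$values[[i]]
  bn_mods <- Filter(function(mod) !is.null(mod$run_mean), model$all_modules())
  stopifnot(length(bn_mods) == length(state$running))
  for (i in seq_along(bn_mods)) {
    bn_mods[[i]]$run_mean <- state$running[[i]]$mean
    bn_mods[[i]]$run_var <- state$running[[i]]$var
  }
  invisible(model)
}

# input shaping helpers
as_spec_batch <- function(x, side) {
  if (is.matrix(x)) x <- list(x)
  if (is.list(x)) {
    B <- length(x)
    out <- array(0, dim = c(side, side, 1, B))
    for (i in seq_len(B)) {
      if (!all(dim(x[[i]]) == c(side, side)))
        stop("spectrogram input must be ", side, " x ", side)
      out[, , 1, i] <- x[[i]]
    }
    return(out)
  }
  if (length(dim(x)) != 4 || dim(x)[1] != side || dim(x)[2] != side ||
      dim(x)[3] != 1)
    stop("spectrogram batch must be (", side, ", ", side, ", 1, B)")
  x
}

as_acc_batch <- function(a, len) {
  if (is.matrix(a)) a <- list(a)
  if (is.list(a)) {
    B <- length(a)
    out <- array(0, dim = c(len, 1, 3, B))
    for (i in seq_len(B)) {
      if (nrow(a[[i]]) != 3 || ncol(a[[i]]) != len)
        stop("accelerometer input must be 3 x ", len)
      out[, 1, , i] <- t(a[[i]])
    }
    return(out)
  }
  if (length(dim(a)) != 4 || dim(a)[1] != len || dim(a)[3] != 3)
    stop("accelerometer batch must be (", len, ", 1, 3, B)")
  a
}

# residual-stage blocks are not exported; all_modules used for optimizer state
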