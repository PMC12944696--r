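# Finite-difference gradient verification of every layer type, then of the
# assembled model.  Tolerances are relative errors against central
# differences at eps = 1e-5.

rng0 <- ecgfuse:::local_rng(99)

test_that("conv2d gradients match finite differences (stride, padding, bias)", {
  set.seed(1)
  for (cfg in list(list(k = 3, s = 1, p = 1), list(k = 5, s = 2, p = 2),
                   list(k = 1, s = 1, p = 0))) {
    l <- ecgfuse:::layer_conv2d(rng0, in_ch = 2, out_ch = 3, kh = cfg$k,
                                stride = cfg$s, pad_h = cfg$p, pad_w = cfg$p)
    x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
    expect_lt(grad_check_layer(l, x), 1e-4)
  }
})

test_that("batch-norm (2d and 1d) gradients match finite differences", {
  # central differences are noisier through the variance normalization, so
  # the tolerance is looser than for the linear layers
  l2 <- ecgfuse:::layer_bn2d(3)
  x <- array(rnorm(4 * 4 * 3 * 3), dim = c(4, 4, 3, 3))
  expect_lt(grad_check_layer(l2, x), 1e-3)
  l1 <- ecgfuse:::layer_bn1d(5)
  xf <- matrix(rnorm(4 * 5), 4, 5)
  expect_lt(grad_check_layer(l1, xf), 1e-3)
})

test_that("max-pool forward equals a direct window maximum and backprops", {
  set.seed(2)
  l <- ecgfuse:::layer_maxpool2d(3L, 3L, 2L, 1L, 1L)
  x <- array(rnorm(7 * 7 * 2 * 2), dim = c(7, 7, 2, 2))
  out <- l$forward(x)
  # direct oracle
  for (b in 1:2) for (cc in 1:2) {
    xp <- matrix(-Inf, 9, 9)
    xp[2:8, 2:8] <- x[, , cc, b]
    for (i in seq_len(dim(out)[1])) for (j in seq_len(dim(out)[2])) {
      win <- xp[(i - 1) * 2 + 1:3, (j - 1) * 2 + 1:3]
      expect_identical(out[i, j, cc, b], max(win))
    }
  }
  expect_lt(grad_check_layer(l, x), 1e-4)
})

test_that("dense, global-average-pool and LSTM layers backprop correctly", {
  set.seed(3)
  ld <- ecgfuse:::layer_dense(rng0, 6, 4)
  expect_lt(grad_check_layer(ld, matrix(rnorm(12), 2, 6)), 1e-4)
  lg <- ecgfuse:::layer_global_avgpool()
  expect_lt(grad_check_layer(lg, array(rnorm(3 * 3 * 2 * 2),
                                       dim = c(3, 3, 2, 2))), 1e-4)
  lc <- ecgfuse:::lstm_cell(rng0, 3, 4)
  expect_lt(grad_check_layer(lc, array(rnorm(5 * 2 * 3), dim = c(5, 2, 3))),
            1e-4)
  lb <- ecgfuse:::layer_bilstm(rng0, 3, 2)
  expect_lt(grad_check_layer(lb, array(rnorm(6 * 2 * 3), dim = c(6, 2, 3))),
            1e-4)
})

test_that("the assembled model gradient matches finite differences", {
  cfg <- model_config(n_classes = 2, input_side = 16, stem_channels = 2,
                      stage_channels = c(2, 3, 3, 4), acc_input_len = 16,
                      acc_channels = c(2, 3, 4), acc_kernels = c(5, 5, 3),
                      lstm_hidden = 3, head_hidden = 5, seed = 7,
                      dropout = 0)
  m <- fusion_model(cfg)
  set.seed(42)
  B <- 3
  spec <- array(rnorm(16 * 16 * B), dim = c(16, 16, 1, B))
  acc <- array(rnorm(16 * 1 * 3 * B), dim = c(16, 1, 3, B))
  labels <- c(0L, 1L, 0L); mot <- c(0L, 2L, 1L)
  tc <- train_config(class_weights = c(1, 2))
  loss_fn <- function() {
    out <- ecgfuse:::model_forward(m, spec, acc, train = TRUE)
    total_loss(out$logits, labels, out$g_ecg, out$g_acc,
               out$motion_logits, mot, tc)
  }
  lo <- loss_fn()
  zero_grads_test(m$params())
  ecgfuse:::model_backward(m, lo$grads$dlogits, lo$grads$dmotion,
                           lo$grads$dg_ecg, lo$grads$dg_acc)
  ps <- m$params()
  eps <- 1e-5
  set.seed(1)
  worst <- 0
  for (p in ps) {
    for (k in sample(length(p$value), min(3, length(p$value)))) {
      v0 <- p$value[k]
      p$value[k] <- v0 + eps; lp <- loss_fn()$total
      p$value[k] <- v0 - eps; lm <- loss_fn()$total
      p$value[k] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - p$grad[k]) /
                     max(1e-6, abs(num) + abs(p$grad[k])))
    }
  }
  expect_lt(worst, 2e-3)
})
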