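toy_m <- fusion_model(toy_model_config(seed = 5))

test_that("encoders produce the configured feature dimensions", {
  cfg <- toy_m$config
  set.seed(1)
  spec <- matrix(rnorm(cfg$input_side^2), cfg$input_side)
  f <- ecg_encode(toy_m, spec)
  expect_equal(dim(f), c(1L, cfg$ecg_feature_dim))
  acc <- matrix(rnorm(3 * cfg$acc_input_len), 3)
  enc <- acc_encode(toy_m, acc)
  expect_equal(dim(enc$f_acc), c(1L, cfg$acc_feature_dim))
  expect_equal(ncol(enc$motion_logits), 4L)
  expect_equal(cfg$fused_dim, cfg$ecg_feature_dim + cfg$acc_feature_dim)
  expect_error(ecg_encode(toy_m, matrix(0, 8, 8)), "must be")
  expect_error(acc_encode(toy_m, matrix(0, 2, cfg$acc_input_len)), "3 x")
})

test_that("full-size layout yields 512/128/640 features and ~11M parameters", {
  m <- fusion_model(model_config(seed = 2))
  set.seed(3)
  spec <- array(rnorm(224 * 224), dim = c(224, 224, 1, 1))
  acc <- array(rnorm(2000 * 3), dim = c(2000, 1, 3, 1))
  out <- ecgfuse:::model_forward(m, spec, acc, train = FALSE)
  expect_equal(ncol(out$f_ecg), 512L)
  expect_equal(ncol(out$f_acc), 128L)
  expect_equal(ncol(out$fused), 640L)
  expect_equal(ncol(out$motion_logits), 4L)
  expect_true(all(is.finite(out$logits)))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  # an 18-layer single-channel residual encoder carries ~11.2M weights
  expect_gt(count_params(m), 10e6)
  expect_lt(count_params(m), 13e6)
  # zero input stays finite
  z <- ecgfuse:::model_forward(m, array(0, dim = c(224, 224, 1, 1)),
                               array(0, dim = c(2000, 1, 3, 1)),
                               train = FALSE)
  expect_true(all(is.finite(z$probs)))
})

test_that("zero-initialized gate maps start at exactly 0.5", {
  m <- fusion_model(toy_model_config(seed = 31))
  set.seed(6)
  B <- 4
  spec <- array(rnorm(32 * 32 * B), dim = c(32, 32, 1, B))
  acc <- array(rnorm(200 * 3 * B), dim = c(200, 1, 3, B))
  out <- ecgfuse:::model_forward(m, spec, acc, train = FALSE)
  expect_identical(unique(out$g_ecg), 0.5)
  expect_identical(unique(out$g_acc), 0.5)
})

test_that("gates stay inside (0,1) and forced gates give identity/null fusion", {
  set.seed(7)
  f_e <- matrix(rnorm(4 * toy_m$config$ecg_feature_dim), 4)
  f_a <- matrix(rnorm(4 * toy_m$config$acc_feature_dim), 4)
  fu <- attention_fuse(toy_m, f_e, f_a)
  expect_true(all(fu$gates$g_ecg > 0 & fu$gates$g_ecg < 1))
  expect_true(all(fu$gates$g_acc > 0 & fu$gates$g_acc < 1))
  ones <- attention_fuse(toy_m, f_e, f_a,
                         force_gates = list(g_ecg = 1, g_acc = 1))
  fe_n <- toy_m$bn_ecg$forward(f_e, train = FALSE)
  fa_n <- toy_m$bn_acc$forward(f_a, train = FALSE)
  expect_equal(ones$fused, cbind(fe_n, fa_n))
  zeros <- attention_fuse(toy_m, f_e, f_a,
                          force_gates = list(g_ecg = 0, g_acc = 0))
  expect_true(all(zeros$fused == 0))
})

test_that("classification head is a proper softmax classifier", {
  set.seed(8)
  fused <- matrix(rnorm(3 * toy_m$config$fused_dim), 3)
  out <- classify_fused(toy_m, fused)
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_equal(out$prediction, max.col(out$probs) - 1L)
  # softmax shift invariance
  sm <- ecgfuse:::softmax_rows
  z <- out$logits
  expect_equal(sm(z + 7), sm(z), tolerance = 1e-12)
  # eval-mode repeatability (dropout inactive)
  expect_identical(out$probs, classify_fused(toy_m, fused)$probs)
})

test_that("the accelerometer encoder is direction-sensitive", {
  set.seed(9)
  acc <- matrix(rnorm(3 * 200), 3)
  f1 <- acc_encode(toy_m, acc)$f_acc
  f2 <- acc_encode(toy_m, acc[, 200:1])$f_acc
  expect_gt(max(abs(f1 - f2)), 1e-8)
})

test_that("evaluation-mode forward is deterministic and fast at batch 16", {
  m <- fusion_model(toy_model_config(seed = 12))
  set.seed(10)
  B <- 16
  spec <- array(rnorm(32 * 32 * B), dim = c(32, 32, 1, B))
  acc <- array(rnorm(200 * 3 * B), dim = c(200, 1, 3, B))
  t0 <- proc.time()
  o1 <- ecgfuse:::model_forward(m, spec, acc, train = FALSE)
  elapsed <- (proc.time() - t0)[3]
  o2 <- ecgfuse:::model_forward(m, spec, acc, train = FALSE)
  expect_identical(o1$probs, o2$probs)
  expect_lt(elapsed, 2)
  # same config seed twice -> identical initialization
  m2 <- fusion_model(toy_model_config(seed = 12))
  o3 <- ecgfuse:::model_forward(m2, spec, acc, train = FALSE)
  expect_identical(o1$probs, o3$probs)
})

test_that("state extraction and restoration reproduce the forward pass", {
  m <- fusion_model(toy_model_config(seed = 21))
  set.seed(11)
  spec <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 1, 2))
  acc <- array(rnorm(200 * 3 * 2), dim = c(200, 1, 3, 2))
  o1 <- ecgfuse:::model_forward(m, spec, acc, train = FALSE)
  st <- model_state(m)
  m2 <- fusion_model(toy_model_config(seed = 22))   # different init
  load_model_state(m2, st)
  o2 <- ecgfuse:::model_forward(m2, spec, acc, train = FALSE)
  expect_equal(o1$probs, o2$probs, tolerance = 1e-12)
})

test_that("posterior refinement behaves at its limits", {
  p <- c(0.7, 0.2, 0.1)
  expect_equal(bayesian_refine(p, temperature = 1), p, tolerance = 1e-12)
  oh <- bayesian_refine(p, activity_prior = c(0, 1, 0), temperature = 1)
  expect_equal(oh, c(0, 1, 0))
  # T -> infinity: result proportional to the prior
  pr <- c(0.5, 0.3, 0.2)
  far <- bayesian_refine(p, activity_prior = pr, temperature = 1e9)
  expect_equal(far, pr, tolerance = 1e-6)
  expect_error(bayesian_refine(p, activity_prior = c(0, 0, 0)), "mass")
  expect_error(bayesian_refine(p, temperature = 0), "positive")
  pm <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(rowSums(bayesian_refine(pm, temperature = 2)), c(1, 1))
})
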