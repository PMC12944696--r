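test_that("gate-diversity hinge reproduces its worked values", {
  # construct gate vectors with an exact target standard deviation
  make_sd <- function(target) {
    g <- c(0.2, 0.4, 0.6, 0.8)
    0.5 + (g - mean(g)) * target / sd(g)
  }
  expect_equal(as.numeric(gate_diversity_loss(make_sd(0.4), make_sd(0.4),
                                              tau = 0.3)), 0)
  expect_equal(as.numeric(gate_diversity_loss(make_sd(0.1), make_sd(0.1),
                                              tau = 0.3)), 0.4,
               tolerance = 1e-12)
  expect_equal(as.numeric(gate_diversity_loss(rep(0.5, 8), rep(0.5, 8),
                                              tau = 0.3)), 0.6,
               tolerance = 1e-12)
  expect_error(gate_diversity_loss(0.5, 0.5), "at least 2")
})

test_that("gate-diversity subgradient matches finite differences", {
  set.seed(14)
  g1 <- runif(6, 0.3, 0.45)                    # sd below tau: active hinge
  g1 <- 0.4 + (g1 - mean(g1)) * 0.1 / sd(g1)
  g2 <- runif(6)
  gl <- gate_diversity_loss(g1, g2, tau = 0.3)
  gr <- attr(gl, "grads")
  eps <- 1e-7
  for (k in c(1, 4)) {
    gp <- g1; gp[k] <- gp[k] + eps
    gm <- g1; gm[k] <- gm[k] - eps
    num <- (as.numeric(gate_diversity_loss(gp, g2, 0.3)) -
              as.numeric(gate_diversity_loss(gm, g2, 0.3))) / (2 * eps)
    expect_equal(gr$dg_ecg[k], num, tolerance = 1e-5)
  }
})

test_that("class weights are majority-normalized inverse frequencies", {
  w <- class_weights_from_distribution(c(0.679, 0.321))
  expect_equal(w[1], 1)
  expect_equal(w[2], 0.679 / 0.321, tolerance = 1e-12)
  expect_equal(w[2], 2.11, tolerance = 0.01)   # printed operating value
  expect_equal(class_weights_from_distribution(c(0.5, 0.5)), c(1, 1))
  fr5 <- c(0.564, 0.002, 0.287, 0.031, 0.116)
  expect_equal(class_weights_from_distribution(fr5), max(fr5) / fr5)
  expect_error(class_weights_from_distribution(c(0.9, 0, 0.1)), "positive")
})

test_that("total loss equals the hand-computed sum of its three components", {
  set.seed(15)
  B <- 6; K <- 2
  logits <- matrix(rnorm(B * K), B)
  labels <- sample(0:1, B, replace = TRUE)
  g_e <- runif(B); g_a <- runif(B)
  mot_logits <- matrix(rnorm(B * 4), B)
  mot_labels <- sample(0:3, B, replace = TRUE)
  cfg <- train_config(class_weights = c(1, 2.11), lambda_gate = 0.1,
                      tau = 0.3, lambda_motion = 0.3)
  lo <- total_loss(logits, labels, g_e, g_a, mot_logits, mot_labels, cfg)
  # independent hand computation
  sm <- function(z) { e <- exp(z - apply(z, 1, max)); e / rowSums(e) }
  p <- sm(logits)
  w <- c(1, 2.11)[labels + 1]
  ce <- sum(w * -log(p[cbind(1:B, labels + 1)])) / sum(w)
  hinge <- max(0, 0.3 - sd(g_e)) + max(0, 0.3 - sd(g_a))
  pm <- sm(mot_logits)
  mce <- mean(-log(pm[cbind(1:B, mot_labels + 1)]))
  expect_equal(lo$total, ce + 0.1 * hinge + 0.3 * mce, tolerance = 1e-12)
  # switch-offs
  cfg0 <- train_config(class_weights = c(1, 2.11), lambda_gate = 0,
                       lambda_motion = 0.3)
  lo0 <- total_loss(logits, labels, g_e, g_a, mot_logits, mot_labels, cfg0)
  expect_equal(lo0$total, ce + 0.3 * mce, tolerance = 1e-12)
  # near-perfect predictions leave only the motion term
  big <- matrix(-20, B, K); big[cbind(1:B, labels + 1)] <- 20
  lop <- total_loss(big, labels, seq(0, 1, length.out = B),
                    seq(1, 0, length.out = B), mot_logits, mot_labels, cfg)
  expect_equal(lop$total, 0.3 * mce, tolerance = 1e-6)
  expect_error(total_loss(logits, c(0L, 5L, rep(0L, 4)), g_e, g_a, cfg = cfg),
               "label outside")
})

test_that("class weighting penalizes an always-majority classifier", {
  labels <- c(rep(0L, 68), rep(1L, 32))
  maj <- matrix(rep(c(5, -5), each = 100), ncol = 2)  # always predicts 0
  unweighted <- ecgfuse:::weighted_ce(maj, labels, NULL)$loss
  weighted <- ecgfuse:::weighted_ce(maj, labels, c(1, 2.11))$loss
  expect_gt(weighted, unweighted)
})

test_that("training is seed-deterministic and early stopping respects patience", {
  task <- small_toy_task()
  run <- function(seed) {
    model <- fusion_model(toy_model_config(seed = seed))
    cfg <- train_config(lr = 1e-3, max_epochs = 1, early_stop_patience = 2,
                        seed = seed)
    train_fusion(model, task$train, task$val, cfg)
  }
  f1 <- run(3); f2 <- run(3)
  expect_identical(f1$history$epochs$train_loss, f2$history$epochs$train_loss)
  # patience 1 with a saturating metric stops quickly
  model <- fusion_model(toy_model_config(seed = 4))
  cfg <- train_config(lr = 1e-3, max_epochs = 6, early_stop_patience = 1,
                      seed = 4)
  fit <- train_fusion(model, task$train, task$val, cfg)
  expect_lte(fit$history$stopped_epoch,
             fit$history$best_epoch + 1L)
  expect_error(train_fusion(fusion_model(toy_model_config()),
                            make_fusion_dataset(list(), list(), integer(0))),
               "empty")
})
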