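test_that("confusion metrics reproduce the published worked example", {
  tab <- reference_table("confusion_clean")
  cm <- as.matrix(tab[, -1])
  met <- confusion_metrics(cm, class_names = tab$true)
  expect_equal(met$accuracy, 99.69)
  expect_equal(met$per_class$precision, c(99.64, 99.81))
  expect_equal(met$per_class$recall, c(99.91, 99.24))
  expect_equal(met$per_class$f1, c(99.77, 99.52))
  ident <- confusion_metrics(diag(c(10, 10)))
  expect_equal(ident$accuracy, 100)
  expect_true(all(ident$per_class$precision == 100))
})

test_that("confusion metrics agree exactly with a per-sample oracle", {
  set.seed(16)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    n <- sample(20:60, 1)
    truth <- sample(0:(k - 1), n, replace = TRUE)
    while (length(unique(truth)) < k)
      truth <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, k)
    met <- suppressWarnings(confusion_metrics(cm))
    # brute force per class
    for (cl in 0:(k - 1)) {
      tp <- sum(truth == cl & pred == cl)
      prec <- if (sum(pred == cl) > 0) 100 * tp / sum(pred == cl) else NaN
      rec <- 100 * tp / sum(truth == cl)
      expect_identical(met$per_class$precision[cl + 1],
                       ecgfuse:::round_half_up(prec, 2))
      expect_identical(met$per_class$recall[cl + 1],
                       ecgfuse:::round_half_up(rec, 2))
    }
    expect_identical(met$accuracy,
                     ecgfuse:::round_half_up(100 * mean(truth == pred), 2))
  }
  expect_warning(confusion_metrics(matrix(c(5, 5, 0, 0), 2)),
                 "never predicted")
  expect_error(confusion_metrics(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "at least one")
})

test_that("trapezoidal AUC equals the pairwise rank oracle, ties included", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:6, n, replace = TRUE)          # heavy ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels), mean(cmp), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  sc <- rnorm(50); lb <- sample(0:1, 50, replace = TRUE)
  lb[1:2] <- 0:1
  expect_equal(roc_auc(exp(sc), lb), roc_auc(sc, lb), tolerance = 1e-12)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC is calibrated on independent scores and matches pROC", {
  set.seed(18)
  n <- 10000
  sc <- rnorm(n); lb <- sample(0:1, n, replace = TRUE)
  expect_equal(roc_auc(sc, lb), 0.5, tolerance = 0.02)
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    sc <- rnorm(300); lb <- rbinom(300, 1, plogis(sc))
    lb[1:2] <- 0:1
    ref <- suppressMessages(as.numeric(pROC::auc(lb, sc)))
    expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
  }
})

test_that("McNemar test matches its formula, the exact fallback, and stats::", {
  a <- c(rep(TRUE, 60), rep(TRUE, 40), rep(FALSE, 10), rep(FALSE, 5))
  b <- c(rep(TRUE, 60), rep(FALSE, 40), rep(TRUE, 10), rep(FALSE, 5))
  res <- mcnemar_paired(a, b)
  expect_equal(res$b, 40); expect_equal(res$c, 10)
  expect_equal(res$chi2, (abs(40 - 10) - 1)^2 / 50)
  expect_equal(res$chi2, 16.82)
  ref <- stats::mcnemar.test(matrix(c(60, 10, 40, 5), 2), correct = TRUE)
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # identical classifiers: degenerate
  same <- mcnemar_paired(a, a)
  expect_equal(same$chi2, 0); expect_equal(same$p, 1)
  # small discordant counts use the exact binomial test
  a2 <- c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 50))
  b2 <- c(rep(FALSE, 5), rep(TRUE, 3), rep(TRUE, 50))
  ex <- mcnemar_paired(a2, b2)
  expect_equal(ex$method, "exact")
  expect_equal(ex$p, stats::binom.test(5, 8, 0.5)$p.value)
  # depends only on (b, c): permuting concordant samples changes nothing
  perm <- sample(which(a == b))
  a3 <- a; b3 <- b
  a3[which(a == b)] <- a[perm]; b3[which(a == b)] <- b[perm]
  expect_equal(mcnemar_paired(a3, b3)$chi2, res$chi2)
})

test_that("trend test is zero under equality and matches stats and permutation", {
  eq <- cochran_armitage(c(80, 80, 80), c(100, 100, 100))
  expect_equal(eq$z, 0); expect_equal(eq$p, 1)
  succ <- c(95, 90, 80, 60); tot <- rep(100, 4)
  ca <- cochran_armitage(succ, tot, scores = 1:4)
  expect_lt(ca$z, 0)                     # accuracy falls as the level rises
  ref <- suppressWarnings(stats::prop.trend.test(succ, tot, score = 1:4))
  expect_equal(ca$z^2, unname(ref$statistic), tolerance = 1e-10)
  # a larger effect gives a larger |Z|
  ca2 <- cochran_armitage(c(95, 85, 70, 40), tot, scores = 1:4)
  expect_gt(abs(ca2$z), abs(ca$z))
  expect_error(cochran_armitage(c(5, 6), c(10, 10)), "3 ordered")
  # permutation oracle on a small table
  set.seed(19)
  succ3 <- c(9, 7, 4); tot3 <- c(12, 12, 12)
  obs <- cochran_armitage(succ3, tot3)$z
  pool <- rep(rep(1:3, tot3), 1)
  y <- unlist(mapply(function(s, t) c(rep(1, s), rep(0, t - s)), succ3, tot3))
  perm_z <- replicate(4000, {
    ys <- sample(y)
    s <- vapply(1:3, function(l) sum(ys[pool == l]), numeric(1))
    cochran_armitage(s, tot3)$z
  })
  p_perm <- mean(abs(perm_z) >= abs(obs) - 1e-12)
  expect_lt(abs(p_perm - cochran_armitage(succ3, tot3)$p), 0.05)
})

test_that("table trends reproduce the published correlation/slope statistics", {
  # y = 2x sanity (lm warns about the perfect fit; that is the point here)
  tt <- suppressWarnings(table_trend(1:10, 2 * (1:10)))
  expect_equal(tt$pearson_r, 1); expect_equal(tt$ols_slope, 2)
  expect_equal(tt$ols_r2, 1)
  # activity table: false-positive rate vs mean accelerometer magnitude
  act <- reference_table("activity_fp")
  expect_equal(round(table_trend(act$accel_mag_g, act$fp_ecg_only_pct)$pearson_r, 3),
               0.992)
  expect_equal(round(table_trend(act$accel_mag_g, act$fp_fusion_pct)$pearson_r, 3),
               0.982)
  # gate means vs SNR level
  gates <- reference_table("gate_by_snr")
  te <- table_trend(gates$snr_db, gates$g_ecg_mean)
  ta <- table_trend(gates$snr_db, gates$g_acc_mean)
  expect_equal(round(te$ols_slope, 4), 0.0023)
  expect_equal(round(ta$ols_slope, 4), -0.0027)
  expect_equal(round(te$ols_r2, 3), 0.982)
  expect_equal(round(ta$ols_r2, 3), 0.973)
  expect_equal(abs(te$spearman_rho), 1)
  expect_equal(abs(ta$spearman_rho), 1)
  expect_error(table_trend(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("gate statistics summarize and stratify consistently", {
  g <- gate_statistics(rep(0.5, 10), rep(0.5, 10))
  expect_equal(g$mean, c(0.5, 0.5)); expect_equal(g$sd, c(0, 0))
  set.seed(20)
  ge <- runif(10000); ga <- runif(10000)
  gs <- gate_statistics(ge, ga)
  expect_equal(gs$mean, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(gs$sd, rep(sqrt(1 / 12), 2), tolerance = 0.01)
  tag <- rep(c("snr6", "snr24"), each = 5000)
  st <- gate_statistics(ge, ga, by = tag)
  expect_equal(nrow(st), 4L)
  sub <- gate_statistics(ge[tag == "snr6"], ga[tag == "snr6"])
  expect_equal(st$mean[st$group == "snr6"], sub$mean)
  expect_equal(st$sd[st$group == "snr6"], sub$sd)
})
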