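#' Confusion matrix from labels and predictions
#'
#' @param truth,pred Integer class ids (0-based) of equal length.
#' @param n_classes Number of classes (default: inferred).
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  stopifnot(length(truth) == length(pred))
  n_classes <- n_classes %||% (max(truth, pred) + 1L)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  dimnames(cm) <- list(true = NULL, predicted = NULL)
  cm
}

#' Per-class metrics from a confusion matrix
#'
#' Precision, recall and F1 per class plus overall accuracy, reported as
#' percentages rounded half-away-from-zero to 2 decimals (the convention of
#' the report tables).  A class never predicted has undefined precision and
#' is reported as `NaN` with a warning.
#'
#' @param cm Square confusion matrix (rows = true, columns = predicted).
#' @param class_names Optional class names.
#' @return List with `per_class` (data frame: class, precision, recall, f1)
#'   and `accuracy` (scalar, percent).
#' @export
confusion_metrics <- function(cm, class_names = NULL) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  if (any(rowSums(cm) == 0)) stop("every class needs at least one true sample")
  k <- nrow(cm)
  diagv <- diag(cm)
  colsum <- colSums(cm)
  if (any(colsum == 0))
    warning("class(es) never predicted; precision undefined (NaN)")
  precision <- ifelse(colsum > 0, diagv / colsum, NaN) * 100
  recall <- diagv / rowSums(cm) * 100
  f1 <- 2 * precision * recall / (precision + recall)
  acc <- sum(diagv) / sum(cm) * 100
  per_class <- data.frame(
    class = class_names %||% paste0("class", seq_len(k) - 1L),
    precision = unname(round_half_up(precision, 2)),
    recall = unname(round_half_up(recall, 2)),
    f1 = unname(round_half_up(f1, 2)),
    row.names = NULL)
  list(per_class = per_class, accuracy = round_half_up(acc, 2))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over thresholds at every distinct score, sweeping the
#' positive-class score.  Score ties are handled by placing both classes'
#' counts on one threshold step, which makes the result identical to the
#' rank (pairwise-comparison) statistic.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 vector (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # counts per distinct score (descending)
  grp <- cumsum(!duplicated(s))
  tp_step <- tapply(y == 1L, grp, sum)
  fp_step <- tapply(y == 0L, grp, sum)
  tpr <- c(0, cumsum(tp_step)) / n_pos
  fpr <- c(0, cumsum(fp_step)) / n_neg
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' McNemar's paired-classifier test
#'
#' Compares two classifiers evaluated on the same samples using the
#' discordant counts `b` (A correct, B wrong) and `c` (A wrong, B correct).
#' The chi-squared statistic uses the continuity correction,
#' `(|b - c| - 1)^2 / (b + c)`, with a p-value from the chi-squared(1) tail;
#' when `b + c < 25` an exact two-sided binomial test is used instead.
#' `b + c = 0` degenerates to `chi2 = 0, p = 1`.
#'
#' @param correct_a,correct_b Logical vectors of per-sample correctness.
#' @return A `paired_comparison` list: `n`, `b`, `c`, `chi2`, `p`, `method`.
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- length(correct_a)
  if (b + cc == 0) {
    out <- list(n = n, b = b, c = cc, chi2 = 0, p = 1, method = "degenerate")
  } else if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    chi2 <- (abs(b - cc) - 1)^2 / (b + cc)
    out <- list(n = n, b = b, c = cc, chi2 = chi2, p = p, method = "exact")
  } else {
    chi2 <- (abs(b - cc) - 1)^2 / (b + cc)
    out <- list(n = n, b = b, c = cc, chi2 = chi2,
                p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                method = "chi2_cc")
  }
  structure(out, class = "paired_comparison")
}

#' Cochran--Armitage trend test
#'
#' Tests for a linear trend in success proportions over ordered levels
#' (e.g. accuracy over SNR levels).  The statistic is
#' `Z = sum_i s_i (x_i - n_i pbar) / sqrt( pbar (1 - pbar) (sum n_i s_i^2 -
#' (sum n_i s_i)^2 / N) )` with level scores `s_i`; the p-value is
#' two-sided normal.  `Z > 0` means the proportion increases with the score.
#'
#' @param successes Integer vector of success counts per level.
#' @param totals Integer vector of trials per level (>= 3 levels).
#' @param scores Numeric level scores (default `seq_along(successes)`).
#' @return List with `z`, `p`.
#' @export
cochran_armitage <- function(successes, totals, scores = seq_along(successes)) {
  stopifnot(length(successes) == length(totals),
            length(scores) == length(totals))
  if (length(totals) < 3) stop("need at least 3 ordered levels")
  N <- sum(totals)
  pbar <- sum(successes) / N
  num <- sum(scores * (successes - totals * pbar))
  den2 <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (den2 <= 0) return(list(z = 0, p = 1))
  z <- num / sqrt(den2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation and trend regression on summary tables
#'
#' Pearson and Spearman correlations plus ordinary-least-squares slope and
#' coefficient of determination of `y` on `x` -- the statistics used to
#' summarize, e.g., gate means against SNR or false-positive rates against
#' motion magnitude.
#'
#' @param x,y Numeric vectors, length >= 3; `x` must have nonzero variance.
#' @return List with `pearson_r`, `spearman_rho`, `ols_slope`, `ols_r2`,
#'   `p_value` (of the slope).
#' @export
table_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       ols_slope = unname(stats::coef(fit)[2]),
       ols_r2 = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}

#' Attention-gate summary statistics
#'
#' Mean, sample standard deviation and range per gate, optionally stratified
#' by a condition tag (SNR level, motion class, ...).
#'
#' @param g_ecg,g_acc Numeric gate values in `[0, 1]`.
#' @param by Optional stratification factor of the same length.
#' @return Data frame with one row per (gate, stratum): `gate`, `group`,
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
gate_statistics <- function(g_ecg, g_acc, by = NULL) {
  stopifnot(length(g_ecg) == length(g_acc), length(g_ecg) > 0)
  by <- if (is.null(by)) factor(rep("all", length(g_ecg))) else factor(by)
  one <- function(g, name) {
    do.call(rbind, lapply(levels(by), function(lv) {
      v <- g[by == lv]
      data.frame(gate = name, group = lv, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 min = min(v), max = max(v), n = length(v))
    }))
  }
  rbind(one(g_ecg, "g_ecg"), one(g_acc, "g_acc"))
}

#' Reference result tables bundled with the package
#'
#' Loads one of the published reference tables shipped under
#' `inst/extdata/` that the worked examples and the report writer reuse:
#' `"confusion_clean"` (held-out clean-test confusion counts),
#' `"gate_by_snr"` (mean attention gates per SNR level),
#' `"activity_fp"` (false-positive rates and motion descriptors per
#' activity), and `"latency"` (per-platform stage latencies in ms).
#'
#' @param name Table name.
#' @return Data frame.
#' @export
reference_table <- function(name = c("confusion_clean", "gate_by_snr",
                                     "activity_fp", "latency")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "ecgfuse", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
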