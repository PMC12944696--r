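#' Expected latency of a two-stage hierarchical classifier
#'
#' The second (expensive, multi-class) stage runs only for beats the first
#' (binary screening) stage flags, so the expected per-beat latency is affine
#' in the arrhythmia prevalence:
#' `T_hier = T_s1 + P(arrhythmia) * T_s2`.
#'
#' @param t_stage1,t_stage2 Stage latencies in ms (>= 0).
#' @param prevalence Arrhythmia prevalence in `[0, 1]`; vectorized.
#' @return Expected latency in ms (not rounded).
#' @export
expected_latency <- function(t_stage1, t_stage2, prevalence) {
  stopifnot(t_stage1 >= 0, t_stage2 >= 0,
            all(prevalence >= 0 & prevalence <= 1))
  t_stage1 + prevalence * t_stage2
}

#' Two-stage hierarchical prediction
#'
#' Runs the binary screening stage on each sample; samples predicted Normal
#' bypass the second stage entirely, the rest get a five-class diagnosis.
#' Stage models are supplied as prediction functions (e.g. closures over a
#' trained [fusion_model()]) mapping a sample to a class id.
#'
#' @param samples List of model inputs.
#' @param stage1_fn Function(sample) -> 0 (Normal) or 1 (Arrhythmia).
#' @param stage2_fn Function(sample) -> class id in 0..4.
#' @param class_names Names of the stage-2 classes (class 0 must be Normal).
#' @return Data frame with `label` (integer final class), `class_name`,
#'   `stages_run` (1 or 2).
#' @export
two_stage_predict <- function(samples, stage1_fn, stage2_fn,
                              class_names = c("Normal", "AF", "VT", "PVC",
                                              "Other")) {
  out <- lapply(samples, function(s) {
    s1 <- stage1_fn(s)
    if (s1 == 0L) list(label = 0L, stages = 1L)
    else list(label = as.integer(stage2_fn(s)), stages = 2L)
  })
  lab <- vapply(out, `[[`, integer(1), "label")
  if (any(lab >= length(class_names)))
    stop("stage-2 label outside the class-name range")
  data.frame(label = lab, class_name = class_names[lab + 1L],
             stages_run = vapply(out, `[[`, integer(1), "stages"))
}

#' Alarm filtering policy
#'
#' @param suppress_accel_threshold Motion-aware suppression threshold on the
#'   accelerometer magnitude, in g (default 0.5).
#' @param critical_classes Class ids that must never be suppressed
#'   (default: the VT-like group, class 2 of the five-class scheme).
#' @param persistence_beats Consecutive arrhythmia beats required before an
#'   alert fires (default 5; conventional range 3--5).
#' @param aggregation_window_s Window for folding non-urgent alerts into
#'   summary records, in seconds (default 3600).
#' @return An `alarm_policy` list.
#' @export
alarm_policy <- function(suppress_accel_threshold = 0.5,
                         critical_classes = 2L,
                         persistence_beats = 5L,
                         aggregation_window_s = 3600) {
  stopifnot(suppress_accel_threshold > 0, persistence_beats >= 1)
  structure(list(suppress_accel_threshold = suppress_accel_threshold,
                 critical_classes = as.integer(critical_classes),
                 persistence_beats = as.integer(persistence_beats),
                 aggregation_window_s = aggregation_window_s),
            class = "alarm_policy")
}

#' Three-tier alarm filtering
#'
#' Applies the alarm policy to a time-aligned stream of per-beat predictions
#' and accelerometer magnitudes:
#'
#' * Tier 1 (motion-aware suppression): non-critical arrhythmia predictions
#'   during high motion (magnitude above the threshold, in g) are suppressed
#'   and logged; critical classes always pass.
#' * Tier 2 (temporal persistence): an alert fires only after
#'   `persistence_beats` consecutive surviving arrhythmia predictions; any
#'   normal (or suppressed) beat resets the counter, and after an alert the
#'   counter re-arms only on a fresh run.
#' * Tier 3 (aggregation): alerts for non-critical classes are folded into
#'   per-window summary counts; critical-class alerts stay real-time.
#'
#' @param predictions Integer class ids per beat (0 = Normal).
#' @param accel_g Accelerometer magnitude per beat, in g (same length).
#' @param beat_times_s Beat times in seconds (same length).
#' @param policy An [alarm_policy()].
#' @return List with `alerts` (data frame: time_s, class, critical),
#'   `suppressed` (data frame: time_s, class, accel_g), and `summaries`
#'   (data frame: window_start_s, class, n_alerts).
#' @export
filter_alarms <- function(predictions, accel_g, beat_times_s, policy) {
  n <- length(predictions)
  if (length(accel_g) != n || length(beat_times_s) != n)
    stop("prediction, accelerometer and time streams must be aligned")
  stopifnot(inherits(policy, "alarm_policy"))
  critical <- predictions %in% policy$critical_classes
  arr <- predictions != 0L
  high_motion <- accel_g > policy$suppress_accel_threshold
  suppress <- arr & high_motion & !critical
  run <- 0L
  alert_rows <- list(); k <- 0L
  for (i in seq_len(n)) {
    if (arr[i] && !suppress[i]) {
      run <- run + 1L
      if (run == policy$persistence_beats) {
        k <- k + 1L
        alert_rows[[k]] <- data.frame(time_s = beat_times_s[i],
                                      class = predictions[i],
                                      critical = critical[i])
        run <- 0L   # re-alert requires a fresh consecutive run
      }
    } else {
      run <- 0L
    }
  }
  alerts <- if (k) do.call(rbind, alert_rows)
  else data.frame(time_s = numeric(0), class = integer(0),
                  critical = logical(0))
  suppressed <- data.frame(time_s = beat_times_s[suppress],
                           class = predictions[suppress],
                           accel_g = accel_g[suppress])
  nc <- alerts[!alerts$critical, , drop = FALSE]
  summaries <- if (nrow(nc)) {
    win <- floor(nc$time_s / policy$aggregation_window_s) *
      policy$aggregation_window_s
    agg <- stats::aggregate(list(n_alerts = rep(1L, nrow(nc))),
                            by = list(window_start_s = win, class = nc$class),
                            FUN = sum)
    agg[order(agg$window_start_s, agg$class), ]
  } else data.frame(window_start_s = numeric(0), class = integer(0),
                    n_alerts = integer(0))
  list(alerts = alerts, suppressed = suppressed, summaries = summaries)
}
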