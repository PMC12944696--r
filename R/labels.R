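#' Beat-label schemes
#'
#' Builds a labelling scheme that maps single-character beat annotation codes
#' to integer class ids.
#'
#' Two schemes are provided, following the AAMI EC57-style groupings used
#' throughout the package:
#'
#' * `"binary"`: class 0 (Normal) = N, L, R, j, e; class 1 (Arrhythmia) =
#'   A, a, J, S, V, E, F, f, /, Q.  With `strict_normal = TRUE` the nodal (j)
#'   and atrial (e) escape beats are excluded from the Normal class instead
#'   (a narrower reading of "normal" limited to N, L, R); they then map to
#'   class 1.
#' * `"five_class"`: 0 Normal = N, L, R; 1 AF-like supraventricular =
#'   A, a, J, S; 2 VT group = F, /, f; 3 PVC = V, E; 4 Other = every other
#'   beat code (Q, j, e, x).
#'
#' Non-beat annotation codes (rhythm changes `+`, noise `~`, artifact `|`,
#' comments `"`) are never classes; [map_labels()] drops them.
#'
#' @param name `"binary"` or `"five_class"`.
#' @param strict_normal Binary scheme only: restrict Normal to N, L, R.
#' @return A `label_scheme` object with elements `name`, `mapping` (named
#'   integer vector, `NA` = excluded), and `class_names`.
#' @export
label_scheme <- function(name = c("binary", "five_class"),
                         strict_normal = FALSE) {
  name <- match.arg(name)
  beat_syms <- c("N", "L", "R", "j", "e", "A", "a", "J", "S", "V", "E",
                 "F", "f", "/", "Q", "x")
  if (name == "binary") {
    normal <- if (strict_normal) c("N", "L", "R") else c("N", "L", "R", "j", "e")
    mapping <- stats::setNames(rep(1L, length(beat_syms)), beat_syms)
    mapping[normal] <- 0L
    class_names <- c("Normal", "Arrhythmia")
  } else {
    mapping <- stats::setNames(rep(4L, length(beat_syms)), beat_syms)
    mapping[c("N", "L", "R")] <- 0L
    mapping[c("A", "a", "J", "S")] <- 1L
    mapping[c("F", "/", "f")] <- 2L
    mapping[c("V", "E")] <- 3L
    class_names <- c("Normal", "AF", "VT", "PVC", "Other")
  }
  structure(list(name = name, mapping = mapping, class_names = class_names),
            class = "label_scheme")
}

#' Map beat annotations to class ids
#'
#' Applies a [label_scheme()] to an annotation table.  Non-beat codes and
#' codes unknown to the scheme are dropped; the number dropped per code is
#' reported in the `dropped` attribute.
#'
#' @param annotations Data frame with columns `sample` and `symbol` (as in an
#'   [ecg_record()]).
#' @param scheme A [label_scheme()].
#' @return Data frame with columns `sample` and `class_id`, plus attribute
#'   `dropped` (named integer vector of dropped counts per code).
#' @export
map_labels <- function(annotations, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  cls <- scheme$mapping[annotations$symbol]
  keep <- !is.na(cls)
  out <- data.frame(sample = annotations$sample[keep],
                    class_id = as.integer(cls[keep]))
  dropped <- table(annotations$symbol[!keep])
  attr(out, "dropped") <- stats::setNames(as.integer(dropped), names(dropped))
  out
}

#' Record-level stratified split
#'
#' Partitions records into train/validation/test sets at the record level so
#' that no subject contributes beats to more than one partition.  Partition
#' sizes follow the requested fractions (largest-remainder rounding, at least
#' one record per partition).  Stratification draws `n_shuffles` seeded random
#' assignments and keeps the one whose per-partition arrhythmia fraction is
#' closest (summed absolute deviation) to the pooled fraction.
#'
#' @param record_ids Character vector of record identifiers (>= 3).
#' @param class_counts Matrix or data frame with one row per record and
#'   columns `n_normal`, `n_arrhythmia` (beat counts used for stratification).
#'   May be `NULL`, in which case the split is random but still deterministic.
#' @param fractions Numeric length-3 vector summing to 1; default
#'   `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed; the split is a pure function of its inputs.
#' @param n_shuffles Number of candidate shuffles scored (default 200).
#' @return A `record_split` list with `train_ids`, `val_ids`, `test_ids`,
#'   and `fractions`.
#' @export
split_records <- function(record_ids, class_counts = NULL,
                          fractions = c(0.70, 0.15, 0.15), seed = 1L,
                          n_shuffles = 200L) {
  n <- length(record_ids)
  if (n < 3) stop("need at least 3 records to form 3 partitions")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  sizes <- partition_sizes(n, fractions)
  if (!is.null(class_counts)) {
    class_counts <- as.data.frame(class_counts)
    stopifnot(nrow(class_counts) == n,
              all(c("n_normal", "n_arrhythmia") %in% names(class_counts)))
    arr <- class_counts$n_arrhythmia
    tot <- class_counts$n_normal + class_counts$n_arrhythmia
  } else {
    arr <- rep(1, n); tot <- rep(2, n)
  }
  global_frac <- sum(arr) / sum(tot)
  best <- NULL; best_score <- Inf
  rng <- local_rng(seed)
  for (k in seq_len(n_shuffles)) {
    perm <- rng$sample(n)
    idx_tr <- perm[seq_len(sizes[1])]
    idx_va <- perm[sizes[1] + seq_len(sizes[2])]
    idx_te <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
    score <- sum(vapply(list(idx_tr, idx_va, idx_te), function(ix) {
      abs(sum(arr[ix]) / max(sum(tot[ix]), 1) - global_frac)
    }, numeric(1)))
    if (score < best_score) {
      best_score <- score
      best <- list(idx_tr, idx_va, idx_te)
    }
  }
  structure(list(train_ids = record_ids[sort(best[[1]])],
                 val_ids = record_ids[sort(best[[2]])],
                 test_ids = record_ids[sort(best[[3]])],
                 fractions = fractions),
            class = "record_split")
}

partition_sizes <- function(n, fractions) {
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- raw - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  # every partition gets at least one record, borrowed from the largest
  while (any(sizes == 0)) {
    i <- which(sizes == 0)[1]
    j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1
    sizes[j] <- sizes[j] - 1
  }
  as.integer(sizes)
}
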