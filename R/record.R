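#' Single-subject recording container
#'
#' An `ecg_record` bundles one subject's single-lead ECG trace (in mV), its
#' sampling rate, the beat annotations, and an optional synchronized tri-axial
#' accelerometer channel.  Annotation indices are 0-based sample positions
#' into the ECG trace; windows elsewhere in the package are half-open
#' `[start, end)`.
#'
#' @param record_id Character scalar identifying the recording.
#' @param ecg Numeric vector of ECG samples in mV.
#' @param fs_ecg ECG sampling rate in Hz (positive scalar).
#' @param annotations Data frame with columns `sample` (0-based integer index,
#'   strictly increasing, within `[0, length(ecg))`) and `symbol`
#'   (single-character beat code).
#' @param accel Optional 3 x N numeric matrix of accelerometer samples in
#'   m/s^2 (rows = x, y, z axes).
#' @param fs_accel Optional accelerometer sampling rate in Hz.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, ecg, fs_ecg, annotations = NULL,
                       accel = NULL, fs_accel = NULL) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  ecg <- as.numeric(ecg)
  if (!is.numeric(fs_ecg) || length(fs_ecg) != 1L || fs_ecg <= 0)
    stop("fs_ecg must be a positive scalar")
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0), symbol = character(0),
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(annotations),
            all(c("sample", "symbol") %in% names(annotations)))
  annotations$sample <- as.integer(annotations$sample)
  annotations$symbol <- as.character(annotations$symbol)
  if (nrow(annotations) > 0) {
    if (any(annotations$sample < 0L) ||
        any(annotations$sample >= length(ecg)))
      stop("annotation sample indices must lie in [0, length(ecg))")
    if (any(diff(annotations$sample) <= 0L))
      stop("annotation sample indices must be strictly increasing")
    if (any(nchar(annotations$symbol) != 1L))
      stop("annotation symbols must be single characters")
  }
  if (!is.null(accel)) {
    accel <- as.matrix(accel)
    if (nrow(accel) != 3L) stop("accel must be a 3 x N matrix")
    if (is.null(fs_accel) || fs_accel <= 0)
      stop("fs_accel must be supplied (and positive) with accel")
  }
  structure(list(record_id = record_id, ecg = ecg, fs_ecg = fs_ecg,
                 annotations = annotations, accel = accel,
                 fs_accel = fs_accel),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz, %d annotations%s>\n",
              x$record_id, length(x$ecg), x$fs_ecg, nrow(x$annotations),
              if (is.null(x$accel)) ""
              else sprintf(", accel 3x%d @ %g Hz", ncol(x$accel),
                           x$fs_accel)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Columnar fixture format: a plain-text serialization used by the synthetic
# fixtures module.  A record <id> is stored as
#   <id>.rec  -- header lines "#key value" (fs_ecg, fs_accel), then a
#                TAB-separated table with columns ecg [, acc_x, acc_y, acc_z]
#                (accelerometer written on its own time base, padded with NA
#                when the two channels differ in length)
#   <id>.ann  -- TAB-separated table with columns sample, symbol
# ---------------------------------------------------------------------------

#' Write a record to disk
#'
#' Serializes a record either in the package's plain-text columnar fixture
#' dialect (default) or as a WFDB-dialect header/signal/annotation triplet.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param format `"columnar"` (plain text) or `"wfdb"`.
#' @return Invisibly, the path of the header/record file written.
#' @export
write_record <- function(record, dir, format = c("columnar", "wfdb")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "wfdb") return(write_record_wfdb(record, dir))
  path <- file.path(dir, paste0(record$record_id, ".rec"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("#fs_ecg %.10g\n", record$fs_ecg), file = con)
  if (!is.null(record$accel))
    cat(sprintf("#fs_accel %.10g\n", record$fs_accel), file = con)
  n_ecg <- length(record$ecg)
  if (is.null(record$accel)) {
    tab <- data.frame(ecg = record$ecg)
  } else {
    n_acc <- ncol(record$accel)
    n <- max(n_ecg, n_acc)
    pad <- function(v, n) c(v, rep(NA_real_, n - length(v)))
    tab <- data.frame(ecg = pad(record$ecg, n),
                      acc_x = pad(record$accel[1, ], n),
                      acc_y = pad(record$accel[2, ], n),
                      acc_z = pad(record$accel[3, ], n))
  }
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  ann_path <- file.path(dir, paste0(record$record_id, ".ann"))
  utils::write.table(record$annotations, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a record from disk
#'
#' Reads either a columnar fixture record (`*.rec` + `*.ann`) or a
#' WFDB-dialect triplet (`*.hea` + `*.dat` + optional `*.atr`).  The format is
#' chosen from the file extension of `path`; a bare path without extension is
#' tried first as columnar, then as WFDB.
#'
#' @param path Path to the `.rec` or `.hea` file (extension may be omitted).
#' @return An [ecg_record()].
#' @export
read_record <- function(path) {
  if (grepl("\\.hea$", path)) return(read_record_wfdb(sub("\\.hea$", "", path)))
  if (grepl("\\.rec$", path)) return(read_record_columnar(sub("\\.rec$", "", path)))
  if (file.exists(paste0(path, ".rec"))) return(read_record_columnar(path))
  if (file.exists(paste0(path, ".hea"))) return(read_record_wfdb(path))
  stop("no record found at ", path)
}

read_record_columnar <- function(stem) {
  path <- paste0(stem, ".rec")
  if (!file.exists(path)) stop("missing record file ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (length(m) == 0) NULL else as.numeric(sub(paste0("^#", key, " "), "", m[1]))
  }
  fs_ecg <- get_hdr("fs_ecg")
  if (is.null(fs_ecg)) stop("corrupt record header in ", path, ": no fs_ecg")
  fs_accel <- get_hdr("fs_accel")
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  ecg <- tab$ecg[!is.na(tab$ecg)]
  accel <- NULL
  if (all(c("acc_x", "acc_y", "acc_z") %in% names(tab))) {
    keep <- !is.na(tab$acc_x)
    accel <- rbind(tab$acc_x[keep], tab$acc_y[keep], tab$acc_z[keep])
  }
  ann_path <- paste0(stem, ".ann")
  ann <- if (file.exists(ann_path)) {
    utils::read.table(ann_path, header = TRUE, sep = "\t",
                      colClasses = c("integer", "character"),
                      comment.char = "")
  } else NULL
  ecg_record(basename(stem), ecg, fs_ecg, annotations = ann,
             accel = accel, fs_accel = fs_accel)
}

# ---------------------------------------------------------------------------
# Minimal WFDB dialect: single-segment headers, one ECG signal in format 16
# (little-endian int16) or 212 (packed 12-bit pairs), MIT-format annotations.
# Enough to round-trip package fixtures and to read standard arrhythmia
# database records when the user has them locally.
# ---------------------------------------------------------------------------

write_record_wfdb <- function(record, dir) {
  id <- record$record_id
  gain <- 200  # adu per mV, the conventional default
  adc_zero <- 0
  samples <- as.integer(round(record$ecg * gain))
  samples <- pmax(pmin(samples, 32767L), -32768L)
  hea <- file.path(dir, paste0(id, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", id, record$fs_ecg, length(samples)),
               sprintf("%s.dat 16 %d %d %d %d %d 0 ECG", id, gain, 16,
                       adc_zero, samples[1], 0L)),
             hea)
  writeBin(samples, file.path(dir, paste0(id, ".dat")), size = 2,
           endian = "little")
  if (nrow(record$annotations) > 0)
    write_wfdb_annotations(record$annotations,
                           file.path(dir, paste0(id, ".atr")))
  invisible(hea)
}

read_record_wfdb <- function(stem) {
  hea_path <- paste0(stem, ".hea")
  if (!file.exists(hea_path)) stop("missing WFDB header ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  head_fields <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(head_fields) < 4) stop("corrupt WFDB header ", hea_path)
  n_sig <- as.integer(head_fields[2])
  fs <- as.numeric(strsplit(head_fields[3], "/")[[1]][1])
  n_samp <- as.integer(head_fields[4])
  if (is.na(n_sig) || n_sig < 1) stop("corrupt WFDB header ", hea_path)
  sig <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  dat_file <- file.path(dirname(stem), sig[1])
  fmt <- sub("x.*", "", sig[2])
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", sig[3])))
  if (is.na(gain) || gain == 0) gain <- 200
  adc_zero <- if (length(sig) >= 5) as.numeric(sig[5]) else 0
  raw_len <- file.info(dat_file)$size
  adus <- switch(fmt,
    "16" = {
      v <- readBin(dat_file, "integer", n = raw_len / 2, size = 2,
                   endian = "little")
      matrix(v, nrow = n_sig)
    },
    "212" = read_dat_212(dat_file, n_sig),
    stop("unsupported WFDB signal format ", fmt))
  ecg <- (adus[1, ] - adc_zero) / gain
  if (!is.na(n_samp) && n_samp > 0) ecg <- ecg[seq_len(min(n_samp, length(ecg)))]
  atr_path <- paste0(stem, ".atr")
  ann <- if (file.exists(atr_path)) read_wfdb_annotations(atr_path) else NULL
  if (!is.null(ann) && nrow(ann) > 0 && any(ann$sample >= length(ecg)))
    stop("annotation indices out of signal range in ", atr_path)
  ecg_record(basename(stem), ecg, fs, annotations = ann)
}

read_dat_212 <- function(path, n_sig) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n_tri <- length(raw) %/% 3
  raw <- raw[seq_len(n_tri * 3)]
  b <- matrix(as.integer(raw), nrow = 3)
  s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0FL), 8)
  s2 <- b[3, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2, ], 4), 0x0FL), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  inter <- as.vector(rbind(s1, s2))
  matrix(inter, nrow = max(n_sig, 1))
}

# MIT annotation format: 16-bit little-endian words; high 6 bits = code,
# low 10 bits = time increment.  Codes used here cover beat annotations;
# code 0 with increment 0 terminates the stream.  SKIP (59) carries a 4-byte
# absolute time; NUM/SUB/AUX (60/61/62/63) modifiers are parsed and ignored.
wfdb_code_table <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "e" = 34L,
  "f" = 38L, "+" = 28L, "~" = 23L, "|" = 26L, "\"" = 22L, "x" = 37L)

write_wfdb_annotations <- function(ann, path) {
  codes <- wfdb_code_table[ann$symbol]
  if (anyNA(codes))
    stop("cannot encode annotation symbol(s): ",
         paste(unique(ann$symbol[is.na(codes)]), collapse = ", "))
  times <- ann$sample
  dt <- diff(c(0L, times))
  words <- integer(0)
  for (i in seq_along(dt)) {
    d <- dt[i]
    while (d >= 1024L) {
      # SKIP annotation: code 59, increment 0, then 4-byte absolute skip
      words <- c(words, bitwShiftL(59L, 10))
      skip <- min(d, 2147483647L)
      words <- c(words,
                 bitwAnd(bitwShiftR(skip, 16), 0xFFFFL),
                 bitwAnd(skip, 0xFFFFL))
      d <- d - skip
    }
    words <- c(words, bitwOr(bitwShiftL(codes[i], 10), d))
  }
  words <- c(words, 0L)
  bytes <- as.raw(as.vector(rbind(bitwAnd(words, 0xFFL),
                                  bitwShiftR(words, 8))))
  writeBin(bytes, path)
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n_w <- length(raw) %/% 2
  lo <- as.integer(raw[seq(1, 2 * n_w, 2)])
  hi <- as.integer(raw[seq(2, 2 * n_w, 2)])
  words <- lo + bitwShiftL(hi, 8)
  code <- bitwShiftR(words, 10)
  incr <- bitwAnd(words, 0x3FFL)
  sym_of <- names(wfdb_code_table)
  t_cur <- 0L
  out_t <- integer(0); out_s <- character(0)
  i <- 1L
  while (i <= n_w) {
    cd <- code[i]
    if (cd == 0L && incr[i] == 0L) break
    if (cd == 59L) {           # SKIP: next two words hold a 4-byte interval
      skip <- bitwShiftL(words[i + 1L], 16) + words[i + 2L]
      t_cur <- t_cur + skip
      i <- i + 3L
      next
    }
    if (cd %in% c(60L, 61L, 62L, 63L)) {   # NUM/SUB/CHN/AUX modifiers
      if (cd == 63L) i <- i + 1L + (incr[i] + incr[i] %% 2L) %/% 2L
      else i <- i + 1L
      next
    }
    t_cur <- t_cur + incr[i]
    hit <- match(cd, wfdb_code_table)
    out_t <- c(out_t, t_cur)
    out_s <- c(out_s, if (is.na(hit)) "Q" else sym_of[hit])
    i <- i + 1L
  }
  data.frame(sample = out_t, symbol = out_s, stringsAsFactors = FALSE)
}
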