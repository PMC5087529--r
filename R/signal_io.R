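# Reading ECG records (WFDB MIT-dialect and CSV), annotation handling and
# R-peak-aligned beat segmentation.
#
# Sample indices are 0-based throughout this module (the convention of
# WFDB annotation times), and beat windows are half-open:
# [r - pre_samples, r - pre_samples + length).

# MIT annotation codes for the five retained classes
.ann_code_map <- c(N = 1L, L = 2L, R = 3L, V = 5L, A = 8L)
.symbol_class_map <- c(N = "N", L = "LBBB", R = "RBBB", V = "PVC", A = "APC")

#' Construct an ECG record
#'
#' @param samples Numeric amplitude vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param r_peaks 0-based sample indices of annotated R peaks, strictly
#'   increasing, within `[0, length(samples))`.
#' @param labels Per-beat class symbols (N, LBBB, RBBB, PVC, APC).
#' @param n_dropped Count of annotations discarded because their symbol is
#'   not one of the five retained classes.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, r_peaks, labels,
                       n_dropped = 0L) {
  samples <- as.numeric(samples)
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) != length(labels)) {
    stop("every retained label needs a matching r_peak")
  }
  if (length(r_peaks) > 1 && any(diff(r_peaks) <= 0)) {
    stop("r_peaks must be strictly increasing")
  }
  if (length(r_peaks) > 0 &&
      (min(r_peaks) < 0 || max(r_peaks) >= length(samples))) {
    stop("r_peaks out of signal range")
  }
  if (length(r_peaks) == 0L) {
    warning("record contains no retained beats")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 r_peaks = r_peaks,
                 labels = factor(as.character(labels), levels = BEAT_CLASSES),
                 n_dropped = as.integer(n_dropped)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("ECG record:", length(x$samples), "samples @", x$sampling_rate, "Hz;",
      length(x$r_peaks), "annotated beats (", x$n_dropped, "dropped )\n")
  invisible(x)
}

.map_symbols <- function(symbols) {
  cls <- .symbol_class_map[as.character(symbols)]
  keep <- !is.na(cls)
  list(class = unname(cls[keep]), keep = keep,
       n_dropped = sum(!keep))
}

#' Read an ECG record from disk
#'
#' Two formats are supported. `"csv"`: a signal file with header
#' `sample,amplitude` plus a sibling annotation file `<stem>_ann.csv` with
#' header `index,symbol` (0-based indices). `"wfdb"`: an MIT-dialect WFDB
#' record (`.hea` header, `.dat` signal in format 212 or 16, binary `.atr`
#' annotations); `path` is the record path without extension, first signal
#' channel is used. Annotation symbols N, L, R, V, A are retained and
#' mapped to classes N, LBBB, RBBB, PVC, APC; all other symbols are
#' dropped and counted.
#'
#' @param path File path (CSV) or record prefix (WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @param sampling_rate Sampling rate for CSV input (Hz, default 360); the
#'   WFDB header carries its own.
#' @return An [ecg_record()].
#' @export
read_ecg_record <- function(path, format = c("csv", "wfdb"),
                            sampling_rate = 360) {
  format <- match.arg(format)
  if (format == "csv") {
    sig <- utils::read.csv(path)
    if (!all(c("sample", "amplitude") %in% names(sig))) {
      stop("CSV signal file must have header 'sample,amplitude'")
    }
    ann_path <- sub("\\.csv$", "_ann.csv", path)
    if (!file.exists(ann_path)) stop("annotation file not found: ", ann_path)
    ann <- utils::read.csv(ann_path, colClasses = c("integer", "character"))
    if (!all(c("index", "symbol") %in% names(ann))) {
      stop("annotation file must have header 'index,symbol'")
    }
    m <- .map_symbols(ann$symbol)
    ecg_record(sig$amplitude, sampling_rate,
               ann$index[m$keep], m$class, m$n_dropped)
  } else {
    read_wfdb_record(path)
  }
}

# ---- WFDB (MIT dialect) ------------------------------------------------

.read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- list(name = top[1], n_sig = as.integer(top[2]),
              fs = if (length(top) >= 3) as.numeric(top[3]) else 250,
              n_samp = if (length(top) >= 4) as.integer(top[4]) else NA)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain_field <- sig[3]
  gain <- as.numeric(sub("^([-0-9.]+).*", "\\1", gain_field))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_field)) {
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
  } else if (length(sig) >= 5) as.numeric(sig[5]) else 0
  rec$file <- sig[1]
  rec$format <- sub("x.*|:.*|\\+.*", "", sig[2])
  rec$gain <- gain
  rec$baseline <- baseline
  rec
}

.decode_212 <- function(raw, n_samp_total) {
  b <- as.integer(raw)
  n_triplets <- length(b) %/% 3L
  b <- b[seq_len(3L * n_triplets)]
  b1 <- b[seq(1, length(b), 3)]
  b2 <- b[seq(2, length(b), 3)]
  b3 <- b[seq(3, length(b), 3)]
  s1 <- bitwAnd(b2, 15L) * 256L + b1
  s2 <- bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L + b3
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.vector(rbind(s1, s2))
  out[seq_len(min(n_samp_total, length(out)))]
}

#' Read an MIT-dialect WFDB record
#'
#' Minimal reader for `.hea`/`.dat`/`.atr` triplets: signal formats 212
#' and 16, first channel only, MIT binary annotation format.
#'
#' @param prefix Record path without extension.
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(prefix) {
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- .read_wfdb_header(hea)
  dat_path <- file.path(dirname(hea), h$file)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  n_total <- if (is.na(h$n_samp)) NA else h$n_samp * h$n_sig
  adc <- switch(h$format,
    "212" = .decode_212(raw, if (is.na(n_total)) length(raw) * 2 else n_total),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little")
      if (!is.na(n_total)) v[seq_len(min(n_total, length(v)))] else v
    },
    stop("unsupported WFDB signal format: ", h$format))
  # deinterleave, keep channel 1
  if (h$n_sig > 1L) adc <- adc[seq(1L, length(adc), by = h$n_sig)]
  amplitude <- (adc - h$baseline) / h$gain
  ann <- read_wfdb_annotations(paste0(prefix, ".atr"))
  m <- .map_symbols(ann$symbol)
  ecg_record(amplitude, h$fs, ann$index[m$keep], m$class, m$n_dropped)
}

#' Read MIT-format binary annotations
#'
#' Decodes the standard 2-byte annotation words (`A` in the high 6 bits of
#' the second byte, time increment in the remaining 10 + 8 bits), the SKIP
#' pseudo-code (59, 4-byte long interval) and the modifier pseudo-codes
#' NUM/SUB/CHN/AUX (60, 61, 62, 63), stopping at the zero terminator.
#'
#' @param path `.atr` file path.
#' @return Data frame with 0-based `index` and character `symbol` columns.
#' @export
read_wfdb_annotations <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  code_symbol <- structure(names(.ann_code_map), names = .ann_code_map)
  idx <- integer(0); sym <- character(0)
  t <- 0L; i <- 1L
  while (i + 1L <= length(raw)) {
    b1 <- raw[i]; b2 <- raw[i + 1L]
    a <- bitwShiftR(b2, 2L)
    interval <- bitwAnd(b2, 3L) * 256L + b1
    i <- i + 2L
    if (a == 0L && interval == 0L) break
    if (a == 59L) {           # SKIP: next 4 bytes hold a long interval
      if (i + 3L > length(raw)) break
      w1 <- raw[i + 1L] * 256L + raw[i]
      w2 <- raw[i + 3L] * 256L + raw[i + 2L]
      t <- t + w1 * 65536L + w2
      i <- i + 4L
    } else if (a %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: no time advance
    } else if (a == 63L) {    # AUX: interval = byte count, padded to even
      i <- i + interval + interval %% 2L
    } else {
      t <- t + interval
      idx <- c(idx, t)
      sym <- c(sym, if (as.character(a) %in% names(code_symbol))
                      code_symbol[[as.character(a)]] else "?")
    }
  }
  data.frame(index = idx, symbol = sym, stringsAsFactors = FALSE)
}

#' Write an ECG record as WFDB (format 16) plus MIT annotations
#'
#' Companion writer used for round-trips and fixtures; quantizes with the
#' given gain.
#'
#' @param record An [ecg_record()].
#' @param prefix Output record path without extension.
#' @param gain ADC units per signal unit (default 200).
#' @return `prefix`, invisibly.
#' @export
write_wfdb_record <- function(record, prefix, gain = 200) {
  adc <- as.integer(round(record$samples * gain))
  dat <- paste0(basename(prefix), ".dat")
  writeLines(c(sprintf("%s 1 %g %d", basename(prefix),
                       record$sampling_rate, length(adc)),
               sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 ECG", dat, gain,
                       adc[1])),
             paste0(prefix, ".hea"))
  writeBin(adc, file.path(dirname(paste0(prefix, ".hea")), dat),
           size = 2L, endian = "little")
  # annotations
  symbols <- names(.symbol_class_map)[match(as.character(record$labels),
                                            .symbol_class_map)]
  bytes <- integer(0)
  t_prev <- 0L
  for (k in seq_along(record$r_peaks)) {
    dt <- record$r_peaks[k] - t_prev
    t_prev <- record$r_peaks[k]
    code <- .ann_code_map[[symbols[k]]]
    if (dt < 1024L) {
      bytes <- c(bytes, dt %% 256L, code * 4L + dt %/% 256L)
    } else {
      w1 <- dt %/% 65536L; w2 <- dt %% 65536L
      bytes <- c(bytes,
                 0L, 59L * 4L,                          # SKIP pseudo-code
                 w1 %% 256L, w1 %/% 256L,               # long interval
                 w2 %% 256L, w2 %/% 256L,
                 0L, code * 4L)                         # event, dt = 0
    }
  }
  bytes <- c(bytes, 0L, 0L)
  writeBin(as.raw(bytes), paste0(prefix, ".atr"))
  invisible(prefix)
}

#' Write an ECG record as CSV (+ sibling annotation file)
#'
#' @param record An [ecg_record()].
#' @param path Signal CSV path; annotations go to `<stem>_ann.csv`.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  utils::write.csv(data.frame(sample = seq_along(record$samples) - 1L,
                              amplitude = record$samples),
                   path, row.names = FALSE, quote = FALSE)
  symbols <- names(.symbol_class_map)[match(as.character(record$labels),
                                            .symbol_class_map)]
  utils::write.csv(data.frame(index = record$r_peaks, symbol = symbols),
                   sub("\\.csv$", "_ann.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment an ECG record into fixed-length R-aligned beats
#'
#' Each beat is the half-open window
#' `samples[r - pre_samples, r - pre_samples + length)` (0-based). Beats
#' whose window would cross a signal boundary are dropped.
#'
#' @param record An [ecg_record()].
#' @param length Samples per beat (default 250).
#' @param pre_samples Samples before the R peak (default 100); must
#'   satisfy `0 < pre_samples < length`.
#' @return A `beat_matrix`; `source_ids` carry the originating R-peak
#'   index, and `attr(, "n_dropped")` counts boundary-dropped beats.
#' @export
segment_beats <- function(record, length = 250L, pre_samples = 100L) {
  stopifnot(inherits(record, "ecg_record"))
  length <- as.integer(length); pre_samples <- as.integer(pre_samples)
  if (length < 2L) stop("length must be >= 2")
  if (pre_samples <= 0L || pre_samples >= length) {
    stop("pre_samples must satisfy 0 < pre_samples < length")
  }
  n <- base::length(record$samples)
  start <- record$r_peaks - pre_samples            # 0-based window start
  ok <- start >= 0L & (start + length) <= n
  rows <- lapply(which(ok), function(k) {
    record$samples[(start[k] + 1L):(start[k] + length)]
  })
  bm <- beat_matrix(do.call(rbind, rows),
                    as.character(record$labels)[ok],
                    sprintf("r%d", record$r_peaks[ok]))
  attr(bm, "n_dropped") <- sum(!ok)
  bm
}

#' Write a beat matrix as CSV
#'
#' One row per beat: 250 sample columns (`s1`..`s250`) plus a `label`
#' column.
#'
#' @param beats A `beat_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  df <- as.data.frame(beats$data)
  names(df) <- paste0("s", seq_len(ncol(df)))
  df$label <- as.character(beats$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beat matrix written by [write_beats_csv()]
#'
#' @param path CSV path.
#' @return A `beat_matrix`.
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path)
  lab <- df$label
  df$label <- NULL
  beat_matrix(as.matrix(df), lab)
}
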