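#' Event / epoch table
#'
#' Rows of (label, onset, duration) marking trials, baseline and recovery
#' periods, or counting intervals within one recording. Rows must not
#' overlap and durations must be positive.
#'
#' @param label Character condition or period names.
#' @param onset_ms Onsets in ms.
#' @param duration_ms Durations in ms (> 0).
#' @return A `data.frame` of class `event_table` with columns `label`,
#'   `onset_ms`, `duration_ms`.
#' @export
event_table <- function(label, onset_ms, duration_ms) {
  df <- data.frame(label = as.character(label),
                   onset_ms = as.numeric(onset_ms),
                   duration_ms = as.numeric(duration_ms),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$onset_ms)) || any(!is.finite(df$duration_ms)))
    stop("event onsets and durations must be finite")
  if (any(df$duration_ms <= 0)) stop("event durations must be positive")
  df <- df[order(df$onset_ms), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    ends <- df$onset_ms + df$duration_ms
    if (any(df$onset_ms[-1L] < ends[-nrow(df)] - 1e-9))
      stop("overlapping events")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = NA,
                    check.names = TRUE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("missing column(s) %s in '%s'",
                 paste(miss, collapse = ", "), path))
}

check_numeric_column <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) & !is.na(x))) {
    row <- which(is.na(v) & !is.na(x))[1L]
    stop(sprintf("non-numeric value '%s' in column '%s', row %d of '%s'",
                 x[row], col, row, path))
  }
  v
}

#' Read an ECG trace from delimited text
#'
#' Accepts either a two-column file (time in s, voltage in mV) from which
#' the sampling rate is inferred, or a single voltage column with the
#' sampling rate given explicitly. Times must be strictly increasing and
#' regularly spaced.
#'
#' @param path Path to a delimited text file (TSV or CSV, with header).
#' @param column_map Named character vector mapping roles to column names,
#'   e.g. `c(time = "time_s", voltage = "mv")`. The `time` entry is optional
#'   for single-column files.
#' @param sampling_rate Sampling rate in Hz; required when the file has no
#'   time column, ignored otherwise.
#' @return An [ecg_record()].
#' @export
read_ecg_table <- function(path, column_map = c(time = "time_s", voltage = "mv"),
                           sampling_rate = NULL) {
  df <- read_delim_auto(path)
  vcol <- unname(column_map["voltage"])
  require_columns(df, vcol, path)
  volts <- check_numeric_column(df, vcol, path)
  tcol <- unname(column_map["time"])
  if (!is.na(tcol) && tcol %in% names(df)) {
    tt <- check_numeric_column(df, tcol, path)
    if (any(diff(tt) <= 0)) stop("unsorted input: time column not increasing")
    dt <- diff(tt)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("irregular sampling in time column")
    ecg_record(volts, sampling_rate = 1 / stats::median(dt),
               start_time = tt[1] * 1000)
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate required when no time column is present")
    ecg_record(volts, sampling_rate = sampling_rate)
  }
}

#' Read an event table from delimited text
#'
#' Expects columns `label`, `onset_ms`, `duration_ms`; validates the
#' non-overlap and positive-duration invariants.
#'
#' @param path Path to a delimited text file.
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("label", "onset_ms", "duration_ms"), path)
  event_table(df$label,
              check_numeric_column(df, "onset_ms", path),
              check_numeric_column(df, "duration_ms", path))
}

#' Write / read an R-R interval series as delimited text
#'
#' Columns `onset_ms`, `rr_ms`, `artifact_flag` (0/1). The round trip is
#' bit-exact for ms-resolution series.
#'
#' @param rr An `rr_series`.
#' @param path Output (or input) file path.
#' @return `write_rr` returns `path` invisibly; `read_rr` returns an
#'   `rr_series`.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(onset_ms = rr$onsets, rr_ms = rr$intervals,
                   artifact_flag = as.integer(rr$flags))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("onset_ms", "rr_ms", "artifact_flag"), path)
  rr_series(check_numeric_column(df, "onset_ms", path),
            check_numeric_column(df, "rr_ms", path),
            check_numeric_column(df, "artifact_flag", path) != 0)
}

#' Write an event table as delimited text
#' @param events An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ECG record as two-column delimited text (time_s, mv)
#' @param ecg An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_table <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  t_s <- (ecg$start_time + (seq_along(ecg$samples) - 1L) /
            ecg$sampling_rate * 1000) / 1000
  df <- data.frame(time_s = t_s, mv = ecg$samples)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
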