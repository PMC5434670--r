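#' ECG record
#'
#' Container for a raw single-lead ECG trace: a sampled voltage series (mV)
#' with its sampling rate and the time offset of the first sample.
#'
#' @param samples Numeric vector of voltages (mV), finite, length >= 2.
#' @param sampling_rate Sampling rate in Hz (> 0); 1000 Hz in typical lab
#'   recordings but any positive rate is accepted.
#' @param start_time Time of the first sample in ms (default 0).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("insufficient signal: need at least 2 samples")
  if (!all(is.finite(samples))) stop("ECG samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number (Hz)")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         start_time = as.numeric(start_time)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<ecg_record: %d samples @ %g Hz (%.1f s), start %g ms>\n",
              length(x$samples), x$sampling_rate, dur, x$start_time))
  invisible(x)
}

#' Duration of an ECG record in ms
#' @param ecg An `ecg_record`.
#' @return Span of the record in ms.
#' @export
ecg_duration_ms <- function(ecg) {
  (length(ecg$samples) - 1L) / ecg$sampling_rate * 1000
}

#' R-R interval series
#'
#' Ordered inter-beat intervals with their onset times and per-interval
#' artifact flags. Intervals are stored as positive integers at 1 ms
#' resolution; onset times are consistent with the cumulative intervals
#' (onset[i + 1] = onset[i] + interval[i]).
#'
#' @param onsets Beat onset times in ms, one per interval (the onset of the
#'   beat that starts the interval).
#' @param intervals Inter-beat intervals in ms (positive, integer-valued).
#' @param flags Logical artifact flags, same length as `intervals`
#'   (default all `FALSE`).
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(onsets, intervals, flags = NULL) {
  intervals <- as.numeric(intervals)
  onsets <- as.numeric(onsets)
  n <- length(intervals)
  if (n < 1L) stop("cannot form intervals: empty series")
  if (is.null(flags)) flags <- rep(FALSE, n)
  if (length(onsets) != n) stop("onsets and intervals must have equal length")
  if (length(flags) != n) stop("flags and intervals must have equal length")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("intervals must be positive and finite")
  if (any(abs(intervals - round(intervals)) > 1e-8))
    stop("intervals must be integer ms")
  if (n > 1L && any(abs(diff(onsets) - intervals[-n]) > 1e-6))
    stop("onset times inconsistent with cumulative intervals")
  structure(
    list(onsets = onsets, intervals = round(intervals),
         flags = as.logical(flags)),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series: %d intervals, %.1f s, %d flagged>\n",
              length(x$intervals), sum(x$intervals) / 1000, sum(x$flags)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Beat onset times of an RR series
#'
#' Returns all beat times, i.e. the onsets of every interval plus the beat
#' closing the final interval.
#'
#' @param rr An `rr_series`.
#' @return Numeric vector of beat times in ms (length = intervals + 1).
#' @export
beat_times <- function(rr) {
  n <- length(rr$intervals)
  c(rr$onsets, rr$onsets[n] + rr$intervals[n])
}

#' Detect R-peaks in an ECG record
#'
#' Pan-Tompkins-style detector: the trace is band-pass filtered around the
#' QRS band (5--15 Hz), differentiated and squared, and the smoothed energy
#' is thresholded. Candidate beats closer together than `min_separation`
#' are resolved in favour of the larger energy peak (refractory rule), and
#' each surviving peak is re-localized to the sample of maximum absolute
#' deflection of the raw trace.
#'
#' @param ecg An `ecg_record`.
#' @param min_separation Refractory period in ms (default 300): no two
#'   reported peaks are closer than this.
#' @return Numeric vector of peak times in ms (strictly increasing), at the
#'   record's sample resolution.
#' @export
detect_r_peaks <- function(ecg, min_separation = 300) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (min_separation <= 0) stop("min_separation must be positive")
  fs <- ecg$sampling_rate
  x <- ecg$samples
  if (ecg_duration_ms(ecg) < 2 * min_separation)
    stop("insufficient signal: record shorter than two beats")

  # QRS-band emphasis; upper edge clipped below Nyquist for low-rate records
  hi <- min(15, 0.45 * fs / 2)
  bf <- signal::butter(2, c(5, hi) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x - stats::median(x))
  energy <- c(0, diff(xb))^2
  w <- max(3L, round(0.12 * fs))
  sm <- stats::filter(energy, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)

  peak <- max(sm)
  if (!is.finite(peak) || peak <= 1e-12 * max(1, stats::var(x)) ||
      max(abs(xb)) < 1e-9)
    stop("no beats found")

  thr <- 0.25 * peak
  above <- sm > thr
  # contiguous supra-threshold regions -> one candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(sm[seg])])
  }
  if (!length(cand)) stop("no beats found")

  # refractory: greedy by energy, enforce min separation
  sep_samp <- min_separation / 1000 * fs
  ord <- cand[order(sm[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= sep_samp)) kept <- c(kept, i)
  }
  kept <- sort(kept)

  # re-localize to the maximum absolute deflection of the raw signal,
  # lightly smoothed (15 ms moving average) so sample-level noise does not
  # shift the argmax off the R apex
  r <- max(1L, round(0.05 * fs))
  base <- stats::median(x)
  wr <- max(3L, round(0.015 * fs))
  if (wr %% 2L == 0L) wr <- wr + 1L
  xs <- stats::filter(abs(x - base), rep(1 / wr, wr), sides = 2)
  xs[is.na(xs)] <- 0
  xs <- as.numeric(xs)
  loc <- vapply(kept, function(i) {
    lo <- max(1L, i - r); hi2 <- min(length(x), i + r)
    seg <- lo:hi2
    seg[which.max(xs[seg])]
  }, integer(1))
  loc <- sort(unique(loc))
  # deduplicate after re-localization
  if (length(loc) > 1L) {
    keep <- c(TRUE, diff(loc) >= sep_samp)
    loc <- loc[keep]
  }
  ecg$start_time + (loc - 1L) / fs * 1000
}

#' Build an R-R interval series from R-peak times
#'
#' Intervals are successive peak-to-peak differences rounded to the nearest
#' ms; onsets are the cumulative times implied by the rounded intervals so
#' that the series is internally consistent.
#'
#' @param peaks Strictly increasing peak times in ms (>= 2 peaks).
#' @return An `rr_series` with all flags `FALSE`.
#' @export
rr_from_peaks <- function(peaks) {
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L) stop("cannot form intervals: need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peak times must be strictly increasing")
  intervals <- round(diff(peaks))
  if (any(intervals <= 0)) stop("cannot form intervals: peaks closer than 1 ms")
  n <- length(intervals)
  onsets <- round(peaks[1]) + c(0, cumsum(intervals[-n]))
  rr_series(onsets, intervals)
}

#' Flag artifactual R-R intervals (successive-difference criterion)
#'
#' A transition between adjacent intervals whose absolute difference exceeds
#' `threshold` marks an artifact. Each exceeding transition is attributed to
#' whichever of its two intervals lies farther from the local median of the
#' series (window of 21 intervals); on a tie the later interval is flagged,
#' reflecting the convention that an aberrant beat follows good data. The
#' first interval can only be flagged through its forward transition.
#' Interval values are never modified.
#'
#' @param rr An `rr_series`.
#' @param threshold Successive-difference threshold in ms (default 300).
#' @return The same `rr_series` with recomputed flags.
#' @export
flag_artifacts <- function(rr, threshold = 300) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is.numeric(threshold) || threshold <= 0) stop("invalid threshold")
  v <- rr$intervals
  n <- length(v)
  flags <- rep(FALSE, n)
  if (n >= 2L) {
    for (i in 2:n) {
      if (abs(v[i] - v[i - 1L]) > threshold) {
        win <- max(1L, i - 11L):min(n, i + 10L)
        med <- stats::median(v[win])
        # attribute to the member farther from the local median; tie -> later
        if (abs(v[i - 1L] - med) > abs(v[i] - med)) {
          flags[i - 1L] <- TRUE
        } else {
          flags[i] <- TRUE
        }
      }
    }
  }
  rr$flags <- flags
  rr
}

local_unflagged_median <- function(v, flags, pos, halfwin = 10L) {
  win <- max(1L, min(pos) - halfwin):min(length(v), max(pos) + halfwin)
  ref <- v[win][!flags[win]]
  if (!length(ref)) ref <- v[!flags]
  if (!length(ref)) ref <- v
  stats::median(ref)
}

# split an integer interval into k parts of integer ms preserving the sum
split_integer <- function(value, k) {
  base <- value %/% k
  rem <- value - base * k
  base + c(rep(1L, rem), rep(0L, k - rem))
}

#' Edit flagged R-R artifacts by integer division or summation
#'
#' Resolves each run of flagged intervals against the local median of
#' unflagged neighbours (window of 10 intervals each side, 20% matching
#' tolerance):
#' \itemize{
#'   \item a single long flagged interval consistent with k missed beats
#'     (value / (k+1) within 20% of the local median) is replaced by k+1
#'     integer intervals that preserve its sum exactly (integer division);
#'   \item a flagged run whose sum is within 20% of the local median is
#'     replaced by one interval equal to that sum (summation);
#'   \item a run matching neither pattern is extended by at most one
#'     adjacent unflagged interval on either side and re-tried as a
#'     summation, which resolves beats split across a transition;
#'   \item anything still unmatched is left flagged and surfaced with a
#'     warning, the in-code surrogate for visual inspection.
#' }
#' Total recorded time is preserved exactly by both edit patterns.
#'
#' @param rr An `rr_series` with flags computed (see [flag_artifacts()]).
#' @return An edited `rr_series`; unresolved positions (if any) are kept
#'   flagged and listed in the `"unresolved"` attribute.
#' @export
edit_artifacts <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (!any(rr$flags)) return(rr)
  v <- as.numeric(rr$intervals)
  flags <- rr$flags
  n <- length(v)

  out_v <- numeric(0)
  out_f <- logical(0)
  unresolved <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!flags[i]) {
      out_v <- c(out_v, v[i]); out_f <- c(out_f, FALSE)
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && flags[j + 1L]) j <- j + 1L
    run <- i:j
    med <- local_unflagged_median(v, flags, run)
    tol <- 0.2 * med
    s <- sum(v[run])
    resolved <- FALSE

    if (length(run) == 1L && v[run] > med + tol) {
      k <- round(v[run] / med)
      if (k >= 2 && abs(v[run] / k - med) <= tol) {
        out_v <- c(out_v, split_integer(v[run], k))
        out_f <- c(out_f, rep(FALSE, k))
        resolved <- TRUE
      }
    }
    if (!resolved && abs(s - med) <= tol) {
      out_v <- c(out_v, s); out_f <- c(out_f, FALSE)
      resolved <- TRUE
    }
    if (!resolved) {
      # try absorbing one adjacent unflagged interval on either side
      left_ok <- length(out_v) > 0L && !out_f[length(out_v)]
      right_ok <- j < n && !flags[j + 1L]
      cand <- list()
      if (left_ok) cand$L <- s + out_v[length(out_v)]
      if (right_ok) cand$R <- s + v[j + 1L]
      if (left_ok && right_ok) cand$LR <- s + out_v[length(out_v)] + v[j + 1L]
      fit <- vapply(cand, function(z) abs(z - med), numeric(1))
      ok <- fit <= tol
      if (any(ok)) {
        pick <- names(cand)[which.min(ifelse(ok, fit, Inf))]
        total <- cand[[pick]]
        if (pick %in% c("L", "LR")) {
          out_v <- out_v[-length(out_v)]; out_f <- out_f[-length(out_f)]
        }
        if (pick %in% c("R", "LR")) j <- j + 1L
        out_v <- c(out_v, total); out_f <- c(out_f, FALSE)
        resolved <- TRUE
      }
    }
    if (!resolved) {
      out_v <- c(out_v, v[run]); out_f <- c(out_f, rep(TRUE, length(run)))
      unresolved <- c(unresolved, length(out_v))
    }
    i <- j + 1L
  }

  onsets <- rr$onsets[1] + c(0, cumsum(out_v[-length(out_v)]))
  res <- rr_series(onsets, out_v, out_f)
  if (length(unresolved)) {
    attr(res, "unresolved") <- unresolved
    warning(sprintf(
      "%d flagged interval(s) matched neither edit pattern; left flagged for inspection",
      length(unresolved)))
  }
  res
}
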