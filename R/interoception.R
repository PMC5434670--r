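#' Per-interval heartbeat-counting score
#'
#' Accuracy of silently counted heartbeats against the ECG-recorded
#' reference for one counting interval:
#' `1 - |recorded - counted| / recorded`. The raw expression goes negative
#' when the count exceeds twice the reference; since the score is defined
#' on [0, 1], such values are clamped to 0 with a warning rather than
#' discarded.
#'
#' @param recorded Recorded (reference) beat count, >= 1.
#' @param counted Participant's counted beats, >= 0.
#' @return Score in [0, 1] (vectorized).
#' @export
interval_score <- function(recorded, counted) {
  recorded <- as.numeric(recorded); counted <- as.numeric(counted)
  if (any(recorded < 1)) stop("no reference beats: recorded_beats must be >= 1")
  if (any(counted < 0)) stop("counted_beats must be >= 0")
  s <- 1 - abs(recorded - counted) / recorded
  if (any(s < 0)) {
    warning(sprintf("%d interval score(s) below 0 clamped to 0", sum(s < 0)))
    s[s < 0] <- 0
  }
  s
}

#' Interoceptive-accuracy (heartbeat perception) score
#'
#' Mean of the per-interval scores over the task's counting intervals
#' (four by default: 25, 35, 45 and 100 s in the reference protocol).
#' Higher values indicate smaller discrepancies between recorded and
#' counted heartbeats.
#'
#' @param recorded Recorded beat counts, one per interval.
#' @param counted Counted beats, one per interval.
#' @param n_required Required number of intervals (default 4).
#' @return Scalar score in [0, 1].
#' @export
ia_score <- function(recorded, counted, n_required = 4) {
  if (length(recorded) != length(counted))
    stop("recorded and counted must have equal length")
  if (length(recorded) != n_required)
    stop(sprintf("expected %d intervals, got %d", n_required,
                 length(recorded)))
  mean(interval_score(recorded, counted))
}

#' Recorded beat count within a counting interval
#'
#' Counts beat onsets of the R-R series falling in the half-open window
#' [onset, onset + duration). The series must cover the interval.
#'
#' @param rr An `rr_series`.
#' @param onset_ms Interval onset in ms.
#' @param duration_ms Interval duration in ms (>= 0).
#' @return Integer beat count.
#' @export
recorded_beats_from_rr <- function(rr, onset_ms, duration_ms) {
  stopifnot(inherits(rr, "rr_series"))
  if (duration_ms < 0) stop("duration must be non-negative")
  bt <- beat_times(rr)
  if (onset_ms < bt[1] || onset_ms + duration_ms > bt[length(bt)])
    stop("interval not covered by the R-R series")
  sum(bt >= onset_ms & bt < onset_ms + duration_ms)
}

#' Score a table of counting trials
#'
#' Appends `interval_score` per row and aggregates a per-subject
#' interoceptive-accuracy score.
#'
#' @param trials data.frame with columns `subject`, `interval_s`,
#'   `recorded_beats`, `counted_beats`.
#' @param n_required Intervals required per subject (default 4).
#' @return List with `trials` (input plus `interval_score`) and `subjects`
#'   (`subject`, `ia`).
#' @export
score_counting <- function(trials, n_required = 4) {
  need <- c("subject", "interval_s", "recorded_beats", "counted_beats")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  trials$interval_score <- interval_score(trials$recorded_beats,
                                          trials$counted_beats)
  subj <- unique(trials$subject)
  ia <- vapply(subj, function(s) {
    rows <- trials[trials$subject == s, , drop = FALSE]
    ia_score(rows$recorded_beats, rows$counted_beats, n_required)
  }, numeric(1))
  list(trials = trials,
       subjects = data.frame(subject = subj, ia = unname(ia),
                             stringsAsFactors = FALSE))
}
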