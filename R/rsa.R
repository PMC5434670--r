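#' Interpolate a heart-period series onto a regular grid
#'
#' Linear interpolation of the R-R tachogram: a piecewise-linear function
#' through (beat onset time, interval value) sampled at `grid_rate`. Beyond
#' the first and last beat onset the value is held constant, so the grid
#' covers the full span of the series (last beat time included).
#'
#' @param rr An edited (artifact-free) `rr_series` with at least 2 intervals.
#' @param grid_rate Grid sampling rate in Hz (default 10).
#' @return An object of class `hp_series`: list of `values` (ms),
#'   `grid_rate` (Hz) and `start_ms`.
#' @export
interpolate_heart_period <- function(rr, grid_rate = 10) {
  stopifnot(inherits(rr, "rr_series"))
  if (any(rr$flags))
    warning("interpolating a series with unresolved artifact flags")
  n <- length(rr$intervals)
  if (n < 2L) stop("too short to interpolate")
  span_ms <- (rr$onsets[n] + rr$intervals[n]) - rr$onsets[1]
  step_ms <- 1000 / grid_rate
  if (span_ms < step_ms) stop("too short to interpolate")
  grid <- rr$onsets[1] + step_ms * 0:floor(span_ms / step_ms)
  vals <- stats::approx(rr$onsets, rr$intervals, xout = grid, rule = 2)$y
  structure(list(values = vals, grid_rate = grid_rate,
                 start_ms = rr$onsets[1]),
            class = "hp_series")
}

#' @export
print.hp_series <- function(x, ...) {
  cat(sprintf("<hp_series: %d samples @ %g Hz, start %g ms>\n",
              length(x$values), x$grid_rate, x$start_ms))
  invisible(x)
}

#' Grid times of a heart-period series (ms)
#' @param hp An `hp_series`.
#' @return Numeric vector of sample times in ms.
#' @export
hp_times <- function(hp) {
  hp$start_ms + (seq_along(hp$values) - 1L) * 1000 / hp$grid_rate
}

#' Design the respiratory-band FIR filter
#'
#' Linear-phase band-pass FIR, windowed-sinc (Hamming) design, used to
#' isolate heart-period variability in the spontaneous-respiration band.
#' The defaults (241 taps, 0.12--0.40 Hz at a 10 Hz grid) give < 1%
#' passband ripple at the band centre, > 40 dB rejection of DC and of
#' slow trends below 0.05 Hz, and > 50 dB above 0.5 Hz.
#'
#' @param grid_rate Sampling rate of the target grid in Hz (default 10).
#' @param taps Number of coefficients; must be odd (default 241).
#' @param band Pass band in Hz (default `c(0.12, 0.40)`), within
#'   (0, grid_rate/2).
#' @return An object of class `band_filter`: `coefficients`, `band`,
#'   `grid_rate`.
#' @export
design_band_filter <- function(grid_rate = 10, taps = 241,
                               band = c(0.12, 0.40)) {
  if (taps %% 2 != 1) stop("invalid filter spec: taps must be odd")
  nyq <- grid_rate / 2
  if (length(band) != 2 || band[1] <= 0 || band[2] >= nyq ||
      band[1] >= band[2])
    stop("invalid filter spec: band must lie within (0, grid_rate/2)")
  h <- signal::fir1(taps - 1L, band / nyq, type = "pass")
  structure(list(coefficients = as.numeric(h), band = band,
                 grid_rate = grid_rate),
            class = "band_filter")
}

#' @export
print.band_filter <- function(x, ...) {
  cat(sprintf("<band_filter: %d taps, %.2f-%.2f Hz @ %g Hz grid>\n",
              length(x$coefficients), x$band[1], x$band[2], x$grid_rate))
  invisible(x)
}

#' Frequency response magnitude of a band filter
#' @param filter A `band_filter`.
#' @param freqs Frequencies in Hz at which to evaluate the gain.
#' @return Magnitude gain at each frequency.
#' @export
filter_gain <- function(filter, freqs) {
  h <- filter$coefficients
  k <- seq_along(h) - 1L
  vapply(freqs, function(f) {
    Mod(sum(h * exp(-2i * pi * f * k / filter$grid_rate)))
  }, numeric(1))
}

#' Apply a band filter to a heart-period series
#'
#' Zero-phase application of the symmetric FIR by centred convolution; the
#' first and last (taps-1)/2 samples are not covered by the filter support
#' and are returned as `NA`. The whole record is filtered once; epochs are
#' cut afterwards.
#'
#' @param hp An `hp_series`.
#' @param filter A `band_filter` designed at the same grid rate.
#' @return An `hp_series` of band-passed values (`NA` in the edge margins).
#' @export
apply_band_filter <- function(hp, filter) {
  stopifnot(inherits(hp, "hp_series"), inherits(filter, "band_filter"))
  if (abs(hp$grid_rate - filter$grid_rate) > 1e-9)
    stop("filter grid rate does not match series grid rate")
  filt <- stats::filter(hp$values, filter$coefficients, sides = 2)
  structure(list(values = as.numeric(filt), grid_rate = hp$grid_rate,
                 start_ms = hp$start_ms),
            class = "hp_series")
}

#' RSA per epoch: natural log of band-passed heart-period variance
#'
#' Filters the full series once, then for each epoch computes the
#' population variance of the filtered signal within [onset, onset +
#' duration) and returns its natural log in ln(ms^2).
#'
#' @param hp An `hp_series` (unfiltered heart period).
#' @param filter A `band_filter`.
#' @param epochs An [event_table()] (or data.frame with `label`,
#'   `onset_ms`, `duration_ms`); each epoch must lie inside the filtered
#'   span (the filter's transient margin is excluded).
#' @return A data.frame with columns `label`, `onset_ms`, `duration_ms`,
#'   `rsa_ln_ms2`.
#' @export
band_variance_ln <- function(hp, filter, epochs) {
  stopifnot(inherits(hp, "hp_series"))
  filt <- apply_band_filter(hp, filter)
  tt <- hp_times(filt)
  out <- epochs
  out$rsa_ln_ms2 <- NA_real_
  for (i in seq_len(nrow(epochs))) {
    on <- epochs$onset_ms[i]; du <- epochs$duration_ms[i]
    idx <- which(tt >= on & tt < on + du)
    if (!length(idx) || any(is.na(filt$values[idx])))
      stop(sprintf("epoch not covered: [%g, %g) ms ('%s')",
                   on, on + du, epochs$label[i]))
    raw <- hp$values[idx]
    if (stats::var(raw) == 0)
      stop(sprintf("degenerate epoch: constant heart period in [%g, %g) ms",
                   on, on + du))
    x <- filt$values[idx]
    v <- mean((x - mean(x))^2)
    if (v <= 0)
      stop(sprintf("degenerate epoch: zero band variance in [%g, %g) ms",
                   on, on + du))
    out$rsa_ln_ms2[i] <- log(v)
  }
  class(out) <- "data.frame"
  out
}

#' Average epoch RSA values within a condition
#'
#' Conditions are scored as the arithmetic mean of exactly `n_required`
#' 30 s epoch values (4 trials per condition in the reference design; the
#' 2-min baseline and recovery rests likewise decompose into four 30 s
#' epochs).
#'
#' @param epoch_values Numeric vector of ln(ms^2) epoch values.
#' @param n_required Required epoch count (default 4).
#' @return The mean ln(ms^2) value.
#' @export
average_condition_rsa <- function(epoch_values, n_required = 4) {
  epoch_values <- as.numeric(epoch_values)
  if (length(epoch_values) != n_required)
    stop(sprintf("incomplete condition (%d/%d)",
                 length(epoch_values), n_required))
  mean(epoch_values)
}

#' RSA reactivity: condition minus baseline
#'
#' Negative values indicate vagal suppression relative to rest.
#'
#' @param condition_rsa Condition RSA, ln(ms^2).
#' @param baseline_rsa Resting baseline RSA, ln(ms^2).
#' @return `condition_rsa - baseline_rsa` (vectorized).
#' @export
reactivity <- function(condition_rsa, baseline_rsa) {
  stopifnot(all(is.finite(condition_rsa)), all(is.finite(baseline_rsa)))
  condition_rsa - baseline_rsa
}

#' Split long rest periods into fixed-length epochs
#'
#' Baseline and recovery rests (e.g. 2 min) are analysed as consecutive
#' 30 s epochs; trial rows already of `epoch_ms` duration pass through
#' unchanged.
#'
#' @param events An [event_table()].
#' @param epoch_ms Epoch length in ms (default 30000).
#' @return An [event_table()] in which every row has duration `epoch_ms`;
#'   rows whose duration is not a multiple of `epoch_ms` raise an error.
#' @export
split_epochs <- function(events, epoch_ms = 30000) {
  lab <- character(0); on <- numeric(0)
  for (i in seq_len(nrow(events))) {
    k <- events$duration_ms[i] / epoch_ms
    if (abs(k - round(k)) > 1e-9)
      stop(sprintf("event '%s' duration %g ms is not a multiple of %g ms",
                   events$label[i], events$duration_ms[i], epoch_ms))
    k <- round(k)
    lab <- c(lab, rep(events$label[i], k))
    on <- c(on, events$onset_ms[i] + epoch_ms * (seq_len(k) - 1L))
  }
  event_table(lab, on, rep(epoch_ms, length(on)))
}

#' Full RSA pipeline for one recording session
#'
#' Interpolates the edited R-R series to a 10 Hz heart-period grid, filters
#' the whole record with the respiratory-band FIR, computes ln band
#' variance per 30 s epoch, averages the four epochs of each condition
#' (and of baseline/recovery), and derives reactivity as condition minus
#' baseline.
#'
#' @param rr An edited `rr_series`.
#' @param events An [event_table()] whose labels include `baseline` (and
#'   optionally `recovery`); remaining labels are treated as conditions.
#' @param grid_rate,taps,band Filter/grid parameters, see
#'   [design_band_filter()].
#' @param epoch_ms Epoch length in ms (default 30000).
#' @param n_epochs Epochs required per condition (default 4).
#' @return List with `epochs` (per-epoch data.frame), `conditions`
#'   (label, rsa_ln_ms2, n_epochs), and `reactivity` (condition labels with
#'   `reactivity_ln_ms2 = condition - baseline`).
#' @export
rsa_session <- function(rr, events, grid_rate = 10, taps = 241,
                        band = c(0.12, 0.40), epoch_ms = 30000,
                        n_epochs = 4) {
  hp <- interpolate_heart_period(rr, grid_rate)
  filt <- design_band_filter(grid_rate, taps, band)
  epochs <- split_epochs(events, epoch_ms)
  per_epoch <- band_variance_ln(hp, filt, epochs)
  labs <- unique(per_epoch$label)
  cond <- data.frame(label = labs, rsa_ln_ms2 = NA_real_,
                     n_epochs = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    v <- per_epoch$rsa_ln_ms2[per_epoch$label == labs[i]]
    cond$rsa_ln_ms2[i] <- average_condition_rsa(v, n_epochs)
    cond$n_epochs[i] <- length(v)
  }
  base <- cond$rsa_ln_ms2[cond$label == "baseline"]
  react <- NULL
  if (length(base) == 1L) {
    task <- cond[!cond$label %in% c("baseline", "recovery"), , drop = FALSE]
    if (nrow(task)) {
      react <- data.frame(label = task$label,
                          condition_rsa = task$rsa_ln_ms2,
                          baseline_rsa = base,
                          reactivity_ln_ms2 = reactivity(task$rsa_ln_ms2, base),
                          stringsAsFactors = FALSE)
    }
  }
  list(epochs = per_epoch, conditions = cond, reactivity = react)
}
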