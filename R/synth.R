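# run expr with a local RNG stream; the caller's random state is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Simulation spec for a respiratory-modulated R-R series
#'
#' The R-R model is a sinusoid in the respiratory band riding on a constant
#' mean heart period, plus white per-beat noise:
#' `RR_k = mean_rr + rsa_amplitude * sin(2*pi*resp_frequency*t_k) + e_k`.
#' Defaults describe a resting adult: 75 bpm (800 ms), 40 ms respiratory
#' modulation at 0.25 Hz (15 breaths/min), 5 ms beat noise, 5 minutes.
#'
#' @param duration_s Record length in s (default 300).
#' @param mean_rr Mean heart period in ms (default 800).
#' @param rsa_amplitude Respiratory modulation amplitude in ms (default 40).
#' @param resp_frequency Respiratory frequency in Hz, inside (0, 0.5)
#'   (default 0.25).
#' @param noise_sd Per-beat noise SD in ms (default 5).
#' @param seed RNG seed.
#' @return A validated list of class `rr_sim_spec`.
#' @export
rr_sim_spec <- function(duration_s = 300, mean_rr = 800, rsa_amplitude = 40,
                        resp_frequency = 0.25, noise_sd = 5, seed = 1) {
  if (mean_rr <= rsa_amplitude + 3 * noise_sd)
    stop("invalid spec: mean_rr must exceed rsa_amplitude + 3*noise_sd")
  if (resp_frequency <= 0 || resp_frequency >= 0.5)
    stop("invalid spec: resp_frequency must be in (0, 0.5)")
  if (duration_s <= 0) stop("invalid spec: duration must be positive")
  structure(list(duration_s = duration_s, mean_rr = mean_rr,
                 rsa_amplitude = rsa_amplitude,
                 resp_frequency = resp_frequency,
                 noise_sd = noise_sd, seed = seed),
            class = "rr_sim_spec")
}

#' Synthesize an R-R interval series with known respiratory-band content
#'
#' Beats are laid down cumulatively from t = 0 using the sinusoid-plus-noise
#' model of [rr_sim_spec()]. The returned ground truth carries the beat
#' times, the analytic in-band variance of the generating process
#' (`amplitude^2/2` plus the in-band share of the beat noise), and
#' `expected_rsa_ln`: the ln variance the interpolation-plus-FIR estimator
#' is expected to report, which includes the low-pass attenuation of linear
#' tachogram interpolation (amplitude factor `sinc^2(f * mean_rr)`).
#'
#' @param spec An [rr_sim_spec()].
#' @param grid_rate Analysis grid rate used for the analytic noise share
#'   (default 10 Hz).
#' @return List with `rr` (an `rr_series`) and `truth` (list: `beat_times`,
#'   `inband_variance`, `expected_rsa_ln`, `spec`).
#' @export
synth_rr <- function(spec, grid_rate = 10) {
  stopifnot(inherits(spec, "rr_sim_spec"))
  with_seed(spec$seed, {
    end_ms <- spec$duration_s * 1000
    t <- 0
    times <- numeric(0); rrs <- numeric(0)
    repeat {
      rr <- spec$mean_rr +
        spec$rsa_amplitude * sin(2 * pi * spec$resp_frequency * t / 1000) +
        (if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0)
      rr <- max(1, round(rr))
      times <- c(times, t); rrs <- c(rrs, rr)
      t <- t + rr
      if (t >= end_ms) break
    }
    rr_obj <- rr_series(times, rrs)

    f_beat <- 1000 / spec$mean_rr
    band <- c(0.12, 0.40)
    inband_noise <- if (spec$noise_sd > 0)
      spec$noise_sd^2 * (band[2] - band[1]) / (f_beat / 2) else 0
    sig_var <- spec$rsa_amplitude^2 / 2
    # linear interpolation of the tachogram attenuates the respiratory
    # component by sinc^2(f * mean RR) in amplitude
    att_sig <- sinc(spec$resp_frequency * spec$mean_rr / 1000)^4
    att_noise <- sinc(mean(band) * spec$mean_rr / 1000)^4
    expected <- sig_var * att_sig + inband_noise * att_noise
    list(rr = rr_obj,
         truth = list(beat_times = beat_times(rr_obj),
                      inband_variance = sig_var + inband_noise,
                      expected_rsa_ln = if (expected > 0) log(expected) else -Inf,
                      spec = spec))
  })
}

default_qrs_template <- function(sampling_rate, width_ms = 80) {
  # Mexican-hat (Ricker) wavelet: sharp positive peak with small side lobes
  half <- round(width_ms / 2 * sampling_rate / 1000)
  t <- (-half:half) / sampling_rate * 1000          # ms
  s <- width_ms / 8
  (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))
}

#' Synthesize an ECG trace with planted R-peaks
#'
#' Superimposes a QRS-like template (Ricker wavelet by default, 1 mV peak)
#' at each beat time, plus optional Gaussian noise. The planted peak times
#' are returned for detector validation.
#'
#' @param beats An `rr_series` or a numeric vector of beat times in ms.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param template Optional numeric template; its maximum defines the peak.
#' @param noise_sd Additive noise SD in mV (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return List with `ecg` (an [ecg_record()]) and `peaks` (planted peak
#'   times, ms).
#' @export
synth_ecg <- function(beats, sampling_rate = 1000, template = NULL,
                      noise_sd = 0, seed = 1) {
  bt <- if (inherits(beats, "rr_series")) beat_times(beats)
        else as.numeric(beats)
  if (!length(bt)) stop("nothing to synthesize: no beats")
  if (is.null(template)) template <- default_qrs_template(sampling_rate)
  tw_ms <- (length(template) - 1) / sampling_rate * 1000
  if (length(bt) > 1 && tw_ms >= min(diff(bt)))
    stop("template overlap: template wider than the shortest R-R interval")
  peak_off <- which.max(template) - 1L

  with_seed(if (noise_sd > 0) seed else NULL, {
    n <- ceiling((max(bt) + tw_ms + 500) / 1000 * sampling_rate)
    x <- numeric(n)
    for (b in bt) {
      ctr <- round(b / 1000 * sampling_rate) + 1L
      idx <- ctr - peak_off + seq_along(template) - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + template[ok]
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    planted <- round(bt / 1000 * sampling_rate) / sampling_rate * 1000
    list(ecg = ecg_record(x, sampling_rate), peaks = planted)
  })
}

#' Corrupt an R-R series with known artifacts
#'
#' `missed_beat` merges the interval at each position with its right
#' neighbour (the detector skipped a beat); `spurious_beat` splits the
#' interval at a random point drawn uniformly from its central 20--80%
#' (a false extra detection). The truth log records every corruption, so
#' editing can be validated against ground truth.
#'
#' @param rr An `rr_series`.
#' @param kind `"missed_beat"` or `"spurious_beat"`.
#' @param positions Interval positions to corrupt (interior: not the first
#'   or last interval).
#' @param seed RNG seed (split points of `spurious_beat`).
#' @return List with `rr` (corrupted series, flags all `FALSE`) and
#'   `truth` (data.frame: `position`, `kind`, `original`).
#' @export
inject_artifacts <- function(rr, kind = c("missed_beat", "spurious_beat"),
                             positions, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  if (!length(positions))
    return(list(rr = rr, truth = data.frame(position = integer(0),
                                            kind = character(0),
                                            original = character(0))))
  if (any(positions <= 1L | positions >= n))
    stop("cannot corrupt boundary interval")
  positions <- sort(unique(positions))
  with_seed(seed, {
    v <- rr$intervals
    truth <- NULL
    if (kind == "missed_beat") {
      for (p in rev(positions)) {
        truth <- rbind(data.frame(position = p, kind = kind,
                                  original = paste(v[p], v[p + 1L],
                                                   sep = "+")),
                       truth)
        v <- c(v[seq_len(p - 1L)], v[p] + v[p + 1L],
               v[seq_len(n)[-seq_len(p + 1L)]])
        n <- length(v)
      }
    } else {
      for (p in rev(positions)) {
        u <- stats::runif(1, 0.2, 0.8)
        a <- max(1L, round(v[p] * u)); b <- v[p] - a
        truth <- rbind(data.frame(position = p, kind = kind,
                                  original = as.character(v[p])),
                       truth)
        v <- c(v[seq_len(p - 1L)], a, b, v[seq_len(n)[-seq_len(p)]])
        n <- length(v)
      }
    }
    onsets <- rr$onsets[1] + c(0, cumsum(v[-length(v)]))
    list(rr = rr_series(onsets, v), truth = truth)
  })
}

#' Simulate heartbeat-counting behaviour
#'
#' For each interval, `counted = round(recorded * (1 - (1 - accuracy) * u))`
#' with `u ~ Uniform(0, 1)`, so the expected interoceptive-accuracy score
#' increases with the `accuracy` parameter (1 = perfect perceiver).
#'
#' @param recorded Recorded beat counts, one per interval.
#' @param accuracy Perceiver accuracy in [0, 1].
#' @param seed RNG seed.
#' @return data.frame with `recorded_beats`, `counted_beats`.
#' @export
synth_counting <- function(recorded, accuracy, seed = 1) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]")
  with_seed(seed, {
    u <- stats::runif(length(recorded))
    counted <- round(recorded * (1 - (1 - accuracy) * u))
    data.frame(recorded_beats = recorded, counted_beats = counted)
  })
}

#' Simulation spec for a two-group cohort
#'
#' Emulates the structure of a patient/control interoception study: per
#' group, (IA, resting RSA) are bivariate normal with a programmable
#' correlation (positive in controls, negative in patients by default),
#' and comfort distance depends linearly on resting RSA with a
#' group-specific slope (nonzero in controls only by default). Covariates
#' are drawn independently. Default moments follow the published cohort:
#' RSA 5.3 vs 3.7 ln(ms^2) (SD 1.6), IA 0.41 vs 0.53 (SD 0.17), and a
#' control-group standardized distance-RSA slope near -0.47.
#'
#' @param n_per_group Subjects per group (>= 4; default 24).
#' @param ia_rsa_correlation Named vector, correlation per group
#'   (default `c(HC = 0.4, AN = -0.4)`).
#' @param distance_rsa_slope cm change per ln(ms^2) of resting RSA
#'   (default `c(HC = -9, AN = 0)`).
#' @param rsa_mean,rsa_sd Resting RSA moments per group, ln(ms^2).
#' @param ia_mean,ia_sd IA moments per group (IA clamped to [0, 1]).
#' @param distance_intercept Comfort-distance intercepts in cm.
#' @param distance_noise_sd Residual SD of comfort distance in cm.
#' @param seed RNG seed.
#' @return A validated list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_per_group = 24,
                            ia_rsa_correlation = c(HC = 0.4, AN = -0.4),
                            distance_rsa_slope = c(HC = -9, AN = 0),
                            rsa_mean = c(HC = 5.3, AN = 3.7),
                            rsa_sd = c(HC = 1.6, AN = 1.6),
                            ia_mean = c(HC = 0.41, AN = 0.53),
                            ia_sd = c(HC = 0.17, AN = 0.17),
                            distance_intercept = c(HC = 170, AN = 135),
                            distance_noise_sd = 26,
                            seed = 1) {
  if (n_per_group < 4) stop("invalid spec: n_per_group must be >= 4")
  if (any(abs(ia_rsa_correlation) >= 1))
    stop("invalid correlation spec: |correlation| must be < 1")
  structure(list(n_per_group = n_per_group,
                 ia_rsa_correlation = ia_rsa_correlation,
                 distance_rsa_slope = distance_rsa_slope,
                 rsa_mean = rsa_mean, rsa_sd = rsa_sd,
                 ia_mean = ia_mean, ia_sd = ia_sd,
                 distance_intercept = distance_intercept,
                 distance_noise_sd = distance_noise_sd,
                 seed = seed),
            class = "cohort_sim_spec")
}

#' Synthesize a two-group cohort table with planted structure
#'
#' One row per subject: group, covariates (age, BMI, trait/state anxiety,
#' depression), IA, resting RSA, comfort distance. The truth list carries
#' every planted parameter.
#'
#' @param spec A [cohort_sim_spec()].
#' @return List with `cohort` (data.frame) and `truth` (the spec).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  groups <- names(spec$ia_rsa_correlation)
  cov_means <- list(HC = c(age = 22, bmi = 21.5, stai_trait = 42,
                           stai_state = 36, bdi = 8),
                    AN = c(age = 23, bmi = 16, stai_trait = 61,
                           stai_state = 50, bdi = 27))
  cov_sds <- c(age = 5, bmi = 1.5, stai_trait = 9, stai_state = 9, bdi = 7)
  with_seed(spec$seed, {
    rows <- NULL
    for (g in groups) {
      n <- spec$n_per_group
      rho <- spec$ia_rsa_correlation[[g]]
      # bivariate normal via Cholesky of the 2x2 correlation
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      ia_z <- z1
      rsa_z <- rho * z1 + sqrt(1 - rho^2) * z2
      ia <- pmin(1, pmax(0, spec$ia_mean[[g]] + spec$ia_sd[[g]] * ia_z))
      rsa <- spec$rsa_mean[[g]] + spec$rsa_sd[[g]] * rsa_z
      dist <- spec$distance_intercept[[g]] +
        spec$distance_rsa_slope[[g]] * rsa +
        stats::rnorm(n, 0, spec$distance_noise_sd)
      dist <- pmax(20, dist)
      cm <- if (g %in% names(cov_means)) cov_means[[g]] else cov_means[[1L]]
      rows <- rbind(rows, data.frame(
        subject_id = paste0(g, seq_len(n)),
        group = g,
        age = pmax(12, round(stats::rnorm(n, cm["age"], cov_sds["age"]))),
        bmi = round(stats::rnorm(n, cm["bmi"], cov_sds["bmi"]), 1),
        stai_trait = round(stats::rnorm(n, cm["stai_trait"],
                                        cov_sds["stai_trait"])),
        stai_state = round(stats::rnorm(n, cm["stai_state"],
                                        cov_sds["stai_state"])),
        bdi = pmax(0, round(stats::rnorm(n, cm["bdi"], cov_sds["bdi"]))),
        ia = ia, resting_rsa = rsa, comfort_distance = dist,
        stringsAsFactors = FALSE))
    }
    rownames(rows) <- NULL
    list(cohort = rows, truth = spec)
  })
}

#' Synthesize per-subject reactivity cells for the 2 x 2 x 2 design
#'
#' RSA reactivity per (BMI x Distance x Gaze) cell, one row per subject x
#' cell, with a planted four-way interaction: only subjects of
#' `modulating_group` receive an offset `delta` in `modulated_cell`.
#' Variance components follow the published cell summaries (between-subject
#' SD ~0.6 ln-units, within-cell noise ~0.4).
#'
#' @param n_per_group Subjects per group (default 24).
#' @param delta Planted offset in ln(ms^2) (default 1.1, sized so the
#'   four-way interaction is comfortably detectable at n = 24 per group).
#' @param modulating_group Group receiving the offset (default `"HC"`).
#' @param modulated_cell Cell receiving it (default
#'   `c(bmi = "thin", distance = "far", gaze = "gaze")`).
#' @param grand_mean Baseline reactivity level (default -0.4).
#' @param subject_sd,cell_sd Random-effect and residual SDs.
#' @param seed RNG seed.
#' @return List with `data` (long data.frame: `subject`, `group`, `bmi`,
#'   `distance`, `gaze`, `reactivity`) and `truth`.
#' @export
synth_reactivity <- function(n_per_group = 24, delta = 1.1,
                             modulating_group = "HC",
                             modulated_cell = c(bmi = "thin",
                                                distance = "far",
                                                gaze = "gaze"),
                             grand_mean = -0.4, subject_sd = 0.6,
                             cell_sd = 0.4, seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(bmi = c("thin", "fat"),
                        distance = c("far", "near"),
                        gaze = c("gaze", "nogaze"),
                        stringsAsFactors = FALSE)
    out <- NULL
    for (g in c("HC", "AN")) {
      for (s in seq_len(n_per_group)) {
        subj_eff <- stats::rnorm(1, 0, subject_sd)
        y <- grand_mean + subj_eff + stats::rnorm(nrow(grid), 0, cell_sd)
        if (g == modulating_group) {
          hit <- grid$bmi == modulated_cell[["bmi"]] &
            grid$distance == modulated_cell[["distance"]] &
            grid$gaze == modulated_cell[["gaze"]]
          y[hit] <- y[hit] + delta
        }
        out <- rbind(out, cbind(
          data.frame(subject = paste0(g, s), group = g,
                     stringsAsFactors = FALSE),
          grid, data.frame(reactivity = y)))
      }
    }
    rownames(out) <- NULL
    list(data = out,
         truth = list(delta = delta, modulating_group = modulating_group,
                      modulated_cell = modulated_cell,
                      grand_mean = grand_mean))
  })
}

#' Synthesize a full recording session (baseline, trial blocks, recovery)
#'
#' Builds one continuous R-R series whose respiratory-band amplitude
#' switches between a baseline value and per-condition values, plus the
#' matching event table: a 2-min baseline, two blocks (thin, fat) of 16
#' trials of 30 s (4 per distance x gaze condition, 15 s inter-trial
#' intervals), and a 2-min recovery. Condition labels are
#' `block.distance.gaze` (e.g. `"thin.far.gaze"`).
#'
#' @param baseline_amplitude Respiratory amplitude at rest, ms (default 60).
#' @param condition_amplitudes Named vector of amplitudes per condition
#'   label; unnamed scalar recycles to all 8 conditions (default 50).
#' @param mean_rr Mean heart period, ms (default 800).
#' @param resp_frequency Respiratory frequency, Hz (default 0.25).
#' @param noise_sd Per-beat noise SD, ms (default 0).
#' @param lead_in_s Unlabelled rest recorded before the baseline and after
#'   the recovery (default 15 s), so that every scored epoch lies clear of
#'   the band filter's transient margin.
#' @param seed RNG seed.
#' @return List with `rr` (an `rr_series`), `events` (an [event_table()]),
#'   and `truth` (amplitudes per period).
#' @export
synth_session <- function(baseline_amplitude = 60, condition_amplitudes = 50,
                          mean_rr = 800, resp_frequency = 0.25,
                          noise_sd = 0, lead_in_s = 15, seed = 1) {
  conds <- as.vector(outer(
    c("far.gaze", "far.nogaze", "near.gaze", "near.nogaze"),
    c("thin", "fat"), function(c2, b) paste(b, c2, sep = ".")))
  if (length(condition_amplitudes) == 1L && is.null(names(condition_amplitudes)))
    condition_amplitudes <- stats::setNames(rep(condition_amplitudes, 8), conds)
  missing_conds <- setdiff(conds, names(condition_amplitudes))
  if (length(missing_conds))
    stop(sprintf("no amplitude for condition(s): %s",
                 paste(missing_conds, collapse = ", ")))

  # period schedule: label, duration; NA label = unscored rest / ITI
  sched <- data.frame(label = NA_character_, dur = lead_in_s * 1000,
                      amp = baseline_amplitude, stringsAsFactors = FALSE)
  sched <- rbind(sched,
                 data.frame(label = "baseline", dur = 120000,
                            amp = baseline_amplitude))
  for (blk in c("thin", "fat")) {
    block_conds <- rep(grep(paste0("^", blk, "\\."), conds, value = TRUE),
                       each = 4)
    for (cc in block_conds) {
      sched <- rbind(sched,
                     data.frame(label = cc, dur = 30000,
                                amp = condition_amplitudes[[cc]]),
                     data.frame(label = NA, dur = 15000,
                                amp = baseline_amplitude))
    }
  }
  sched <- rbind(sched,
                 data.frame(label = "recovery", dur = 120000,
                            amp = baseline_amplitude),
                 data.frame(label = NA, dur = lead_in_s * 1000,
                            amp = baseline_amplitude))
  starts <- cumsum(c(0, sched$dur[-nrow(sched)]))
  total <- sum(sched$dur)

  with_seed(seed, {
    amp_at <- function(t) {
      i <- findInterval(t, starts)
      sched$amp[i]
    }
    t <- 0; times <- numeric(0); rrs <- numeric(0)
    repeat {
      rr <- mean_rr + amp_at(t) * sin(2 * pi * resp_frequency * t / 1000) +
        (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
      rr <- max(1, round(rr))
      times <- c(times, t); rrs <- c(rrs, rr)
      t <- t + rr
      if (t >= total) break
    }
    ev <- sched[!is.na(sched$label), , drop = FALSE]
    ev_on <- starts[!is.na(sched$label)]
    list(rr = rr_series(times, rrs),
         events = event_table(ev$label, ev_on, ev$dur),
         truth = list(baseline_amplitude = baseline_amplitude,
                      condition_amplitudes = condition_amplitudes,
                      mean_rr = mean_rr, resp_frequency = resp_frequency))
  })
}
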