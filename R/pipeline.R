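#' Run configuration
#'
#' Central configuration for the pipeline commands. Every numeric default
#' is the protocol's reference value: 1 kHz ECG sampling, a 300 ms
#' successive-difference artifact threshold, a 241-tap 0.12--0.40 Hz FIR
#' on a 10 Hz heart-period grid, 30 s epochs, four counting intervals,
#' the five-covariate ANCOVA set, alpha 0.05 with two planned
#' correlations per family. Overrides are echoed into the run log.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `run_config`.
#' @export
cv_config <- function(...) {
  cfg <- list(
    sampling_rate = 1000,
    artifact_threshold_ms = 300,
    filter_taps = 241,
    filter_band_hz = c(0.12, 0.40),
    grid_rate_hz = 10,
    epoch_ms = 30000,
    epochs_per_condition = 4,
    counting_intervals_s = c(25, 35, 45, 100),
    ancova_covariates = c("age", "bmi", "stai_trait", "stai_state", "bdi"),
    alpha = 0.05,
    planned_correlations = 2,
    reference_hc_r = 0.40,
    reference_hc_n = 23,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
  attr(cfg, "overrides") <- names(over)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) stop("config: sampling_rate must be positive")
  if (cfg$artifact_threshold_ms <= 0)
    stop("config: artifact threshold must be positive")
  if (cfg$filter_taps %% 2 != 1) stop("config: filter_taps must be odd")
  if (cfg$epoch_ms <= 0) stop("config: epoch_ms must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("config: alpha must be in (0, 1)")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#' @param path Path to a YAML file of config overrides.
#' @return A [cv_config()].
#' @export
read_config <- function(path) {
  do.call(cv_config, yaml::read_yaml(path))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

log_lines <- function(path, lines) {
  if (!is.null(path)) cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(lines)
}

start_run_log <- function(out_dir, cfg, command) {
  if (is.null(out_dir)) return(NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "run_log.txt")
  cat(sprintf("# cardiovagal %s | %s | %s\n",
              as.character(utils::packageVersion("cardiovagal")),
              command, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = path)
  over <- attr(cfg, "overrides")
  if (length(over))
    log_lines(path, sprintf("override %s = %s", over,
                            vapply(over, function(nm)
                              paste(format(cfg[[nm]]), collapse = ","),
                              character(1))))
  path
}

#' Preprocess a raw ECG file into an edited R-R series
#'
#' Detects R-peaks, builds the R-R series, flags artifacts with the
#' configured successive-difference threshold, and edits them by integer
#' division / summation. Surfaced (unresolved) flags are written to the
#' run log rather than silently edited.
#'
#' @param ecg_path Path to an ECG text file (see [read_ecg_table()]).
#' @param out_dir Output directory (optional; `rr.tsv` and `run_log.txt`
#'   are written there).
#' @param config A [cv_config()].
#' @return The edited `rr_series`, invisibly when writing.
#' @export
run_preprocess <- function(ecg_path, out_dir = NULL, config = cv_config()) {
  lg <- start_run_log(out_dir, config, "preprocess")
  ecg <- read_ecg_table(ecg_path, sampling_rate = config$sampling_rate)
  rr <- rr_from_peaks(detect_r_peaks(ecg))
  rr <- flag_artifacts(rr, config$artifact_threshold_ms)
  n_flag <- sum(rr$flags)
  rr <- withCallingHandlers(
    edit_artifacts(rr),
    warning = function(w) {
      log_lines(lg, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  log_lines(lg, sprintf("flagged %d interval(s); %d left unresolved",
                        n_flag, sum(rr$flags)))
  if (!is.null(out_dir)) {
    write_rr(rr, file.path(out_dir, "rr.tsv"))
    return(invisible(rr))
  }
  rr
}

#' Compute epoch / condition RSA and reactivity tables
#'
#' @param rr_path Path to an R-R TSV (see [write_rr()]), or an `rr_series`.
#' @param events_path Path to an events TSV, or an [event_table()].
#' @param out_dir Output directory (optional).
#' @param config A [cv_config()].
#' @return The [rsa_session()] result list.
#' @export
run_rsa <- function(rr_path, events_path, out_dir = NULL,
                    config = cv_config()) {
  lg <- start_run_log(out_dir, config, "rsa")
  rr <- if (inherits(rr_path, "rr_series")) rr_path else read_rr(rr_path)
  ev <- if (inherits(events_path, "event_table")) events_path
        else read_events(events_path)
  res <- rsa_session(rr, ev, grid_rate = config$grid_rate_hz,
                     taps = config$filter_taps,
                     band = config$filter_band_hz,
                     epoch_ms = config$epoch_ms,
                     n_epochs = config$epochs_per_condition)
  log_lines(lg, sprintf("computed RSA for %d epochs, %d conditions",
                        nrow(res$epochs), nrow(res$conditions)))
  if (!is.null(out_dir)) {
    utils::write.table(res$epochs, file.path(out_dir, "rsa_epochs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$conditions,
                       file.path(out_dir, "rsa_conditions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$reactivity))
      utils::write.table(res$reactivity,
                         file.path(out_dir, "rsa_reactivity.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' Score a heartbeat-counting trial table
#'
#' @param counting_path Path to a counting TSV (`subject`, `interval_s`,
#'   `recorded_beats`, `counted_beats`) or such a data.frame.
#' @param out_dir Output directory (optional).
#' @param config A [cv_config()].
#' @return The [score_counting()] result; clamped scores are logged.
#' @export
run_ia <- function(counting_path, out_dir = NULL, config = cv_config()) {
  lg <- start_run_log(out_dir, config, "ia")
  trials <- if (is.data.frame(counting_path)) counting_path
            else read_delim_auto(counting_path)
  res <- withCallingHandlers(
    score_counting(trials, n_required = length(config$counting_intervals_s)),
    warning = function(w) {
      log_lines(lg, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  if (!is.null(out_dir)) {
    utils::write.table(res$trials, file.path(out_dir, "ia_trials.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$subjects, file.path(out_dir, "ia_subjects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' Run the cohort-level inferential battery
#'
#' Given a cohort table (one row per subject with `group`, covariates,
#' `ia`, `resting_rsa`, `comfort_distance`), runs: the resting-RSA ANCOVA
#' with the configured covariates and adjusted marginal means; per-group
#' IA--RSA Pearson correlations with a Fisher r-to-z comparison; and
#' per-group regressions of comfort distance on resting RSA.
#'
#' @param cohort_path Path to a cohort delimited file, or a data.frame.
#' @param out_dir Output directory (optional).
#' @param config A [cv_config()].
#' @return List with `ancova`, `correlations`, `fisher`, `regressions`.
#' @export
run_analyze <- function(cohort_path, out_dir = NULL, config = cv_config()) {
  lg <- start_run_log(out_dir, config, "analyze")
  cohort <- if (is.data.frame(cohort_path)) cohort_path
            else read_delim_auto(cohort_path)
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) stop("cohort must contain exactly 2 groups")

  anc <- ancova(cohort, "resting_rsa", "group",
                intersect(config$ancova_covariates, names(cohort)))

  cors <- lapply(groups, function(g) {
    d <- cohort[cohort$group == g, ]
    pearson_cor(d$ia, d$resting_rsa)
  })
  names(cors) <- groups
  fz <- fisher_rz_compare(cors[[1L]]$r, cors[[1L]]$n,
                          cors[[2L]]$r, cors[[2L]]$n)
  regs <- lapply(groups, function(g) {
    d <- cohort[cohort$group == g, ]
    simple_regression(d$comfort_distance, d$resting_rsa)
  })
  names(regs) <- groups

  log_lines(lg, sprintf("groups: %s; ANCOVA group F = %.3f",
                        paste(groups, collapse = ", "),
                        anc$effects$F[anc$effects$term == "group"]))
  res <- list(ancova = anc, correlations = cors, fisher = fz,
              regressions = regs)
  if (!is.null(out_dir)) {
    utils::write.table(anc$effects, file.path(out_dir, "ancova_effects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cor_df <- data.frame(group = groups,
                         r = vapply(cors, `[[`, numeric(1), "r"),
                         n = vapply(cors, `[[`, numeric(1), "n"),
                         p = vapply(cors, `[[`, numeric(1), "p"))
    utils::write.table(cor_df, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' Generate a complete synthetic dataset on disk
#'
#' Emits the same file formats the readers consume: an ECG trace with
#' planted peaks, the R-R and event tables of a full session, a
#' heartbeat-counting table, and a two-group cohort table. End-to-end runs
#' therefore need no real data.
#'
#' @param out_dir Output directory.
#' @param config A [cv_config()]; `config$seed` drives all draws.
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(out_dir, config = cv_config()) {
  lg <- start_run_log(out_dir, config, "simulate")
  seed <- config$seed

  ses <- synth_session(seed = seed)
  write_rr(ses$rr, file.path(out_dir, "rr.tsv"))
  write_events(ses$events, file.path(out_dir, "events.tsv"))

  spec <- rr_sim_spec(duration_s = 60, seed = seed + 1L)
  sr <- synth_rr(spec)
  se <- synth_ecg(sr$rr, sampling_rate = config$sampling_rate,
                  noise_sd = 0.02, seed = seed + 2L)
  write_ecg_table(se$ecg, file.path(out_dir, "ecg.tsv"))

  rec <- round(config$counting_intervals_s * 1000 / 800)
  cnt <- synth_counting(rec, accuracy = 0.7, seed = seed + 3L)
  cnt <- data.frame(subject = "S1", interval_s = config$counting_intervals_s,
                    cnt)
  utils::write.table(cnt, file.path(out_dir, "counting.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  coh <- synth_cohort(cohort_sim_spec(seed = seed + 4L))
  utils::write.table(coh$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_lines(lg, sprintf("simulated dataset written to %s (seed %d)",
                        out_dir, seed))
  invisible(list(rr = file.path(out_dir, "rr.tsv"),
                 events = file.path(out_dir, "events.tsv"),
                 ecg = file.path(out_dir, "ecg.tsv"),
                 counting = file.path(out_dir, "counting.tsv"),
                 cohort = file.path(out_dir, "cohort.tsv")))
}

#' Load the bundled clinical cohort table
#'
#' Twenty-four anorexia-nervosa patients: age, age of illness onset,
#' illness duration (years), interoceptive accuracy, and resting RSA
#' (ln(ms^2)), transcribed from the published cohort table.
#'
#' @return data.frame with columns `id`, `age`, `age_of_onset`,
#'   `illness_duration_years`, `ia`, `resting_rsa`.
#' @export
load_table2 <- function() {
  utils::read.csv(system.file("extdata", "table2_an_patients.csv",
                              package = "cardiovagal", mustWork = TRUE))
}

#' Reproduce the published statistics of the bundled cohort table
#'
#' Recomputes from the bundled patient table: descriptives (mean age,
#' illness duration), Shapiro-Wilk normality gates, the Bonferroni
#' threshold for two planned correlations, mid-rank Spearman correlations
#' of resting RSA and IA with onset age and illness duration, the Pearson
#' correlation between IA and resting RSA, and its Fisher r-to-z
#' comparison against the published control-group coefficient
#' (`config$reference_hc_r`, `config$reference_hc_n`).
#'
#' @param out_dir Output directory (optional).
#' @param config A [cv_config()].
#' @return List of computed results.
#' @export
run_table2 <- function(out_dir = NULL, config = cv_config()) {
  lg <- start_run_log(out_dir, config, "table2")
  t2 <- load_table2()
  gate_onset <- shapiro_wilk(t2$age_of_onset)
  gate_dur <- shapiro_wilk(t2$illness_duration_years)
  res <- list(
    n = nrow(t2),
    mean_age = mean(t2$age),
    mean_illness_duration = mean(t2$illness_duration_years),
    shapiro = list(age_of_onset = gate_onset, illness_duration = gate_dur),
    bonferroni = bonferroni_threshold(config$alpha,
                                      config$planned_correlations),
    spearman_rsa_onset = spearman_cor(t2$resting_rsa, t2$age_of_onset),
    spearman_rsa_duration = spearman_cor(t2$resting_rsa,
                                         t2$illness_duration_years),
    spearman_ia_onset = spearman_cor(t2$ia, t2$age_of_onset),
    spearman_ia_duration = spearman_cor(t2$ia, t2$illness_duration_years),
    pearson_ia_rsa = pearson_cor(t2$ia, t2$resting_rsa))
  res$fisher_vs_reference <- fisher_rz_compare(
    config$reference_hc_r, config$reference_hc_n,
    res$pearson_ia_rsa$r, res$pearson_ia_rsa$n)
  log_lines(lg, c(
    sprintf("n = %d, mean age = %.2f, mean illness duration = %.2f",
            res$n, res$mean_age, res$mean_illness_duration),
    sprintf("r_s(RSA, onset) = %.2f", res$spearman_rsa_onset$r),
    sprintf("r(IA, RSA) = %.2f; z vs reference = %.2f",
            res$pearson_ia_rsa$r, res$fisher_vs_reference$z)))
  if (!is.null(out_dir)) {
    summ <- data.frame(
      quantity = c("n", "mean_age", "mean_illness_duration",
                   "bonferroni_threshold", "spearman_rsa_onset",
                   "spearman_rsa_duration", "spearman_ia_onset",
                   "spearman_ia_duration", "pearson_ia_rsa", "fisher_z"),
      value = c(res$n, res$mean_age, res$mean_illness_duration,
                res$bonferroni, res$spearman_rsa_onset$r,
                res$spearman_rsa_duration$r, res$spearman_ia_onset$r,
                res$spearman_ia_duration$r, res$pearson_ia_rsa$r,
                res$fisher_vs_reference$z))
    utils::write.table(summ, file.path(out_dir, "table2_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}
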