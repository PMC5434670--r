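test_that("planted R-peaks are recovered exactly on clean synthetic ECG", {
  se <- synth_ecg(c(500, 1300, 2100))
  expect_equal(detect_r_peaks(se$ecg), se$peaks, tolerance = 1e-9)

  one <- synth_ecg(2000)
  expect_equal(detect_r_peaks(one$ecg), 2000)

  flat <- ecg_record(rep(0, 10000), 1000)
  expect_error(detect_r_peaks(flat), "no beats found")

  expect_error(detect_r_peaks(ecg_record(c(0, 1, 0), 1000)),
               "insufficient signal")
})

test_that("detector recovers >= 99% of planted peaks under noise", {
  s <- synth_rr(rr_sim_spec(duration_s = 120, noise_sd = 20, seed = 11))
  for (noise in c(0.05, 0.10)) {
    se <- synth_ecg(s$rr, noise_sd = noise, seed = 13)
    pk <- detect_r_peaks(se$ecg)
    hit <- vapply(se$peaks, function(p) min(abs(pk - p)) <= 1, logical(1))
    expect_gte(mean(hit), 0.99)
  }
})

test_that("rr_from_peaks times intervals to the nearest ms", {
  rr <- rr_from_peaks(c(0, 800, 1600))
  expect_equal(rr$intervals, c(800, 800))
  expect_false(any(rr$flags))

  rr2 <- rr_from_peaks(c(0, 800.4, 1600.9))
  expect_equal(rr2$intervals, c(800, 801))
  # onsets consistent with cumulative intervals
  expect_equal(diff(rr2$onsets), rr2$intervals[-length(rr2$intervals)])

  expect_error(rr_from_peaks(0), "cannot form intervals")
  expect_error(rr_from_peaks(c(100, 100)), "strictly increasing")
})

test_that("successive-difference flagging reproduces the canonical cases", {
  rr <- function(v) rr_series(cumsum(c(0, v[-length(v)])), v)
  expect_equal(which(flag_artifacts(rr(c(800, 810, 790)))$flags), integer(0))
  expect_equal(which(flag_artifacts(rr(c(800, 1600, 800)))$flags), 2L)
  expect_equal(which(flag_artifacts(rr(c(800, 400, 400, 800)))$flags),
               c(2L, 4L))
  # an aberrant first interval is caught through its forward transition
  expect_equal(which(flag_artifacts(rr(c(1600, 800, 810, 790)))$flags), 1L)
  # flagging never alters values and is idempotent
  f1 <- flag_artifacts(rr(c(800, 1600, 800)))
  f2 <- flag_artifacts(f1)
  expect_identical(f1$intervals, f2$intervals)
  expect_identical(f1$flags, f2$flags)
  expect_error(flag_artifacts(rr(c(800, 810)), threshold = -5),
               "invalid threshold")
})

test_that("editing resolves long intervals by integer division", {
  rr <- rr_series(c(0, 800, 1600, 3210), c(800, 800, 1610, 795),
                  c(FALSE, FALSE, TRUE, FALSE))
  ed <- edit_artifacts(rr)
  expect_equal(ed$intervals, c(800, 800, 805, 805, 795))
  expect_false(any(ed$flags))
  expect_equal(sum(ed$intervals), sum(rr$intervals))
  # re-flagging the edited series is clean
  expect_false(any(flag_artifacts(ed)$flags))
})

test_that("editing resolves short runs by summation", {
  rr <- rr_series(c(0, 800, 1190, 1600), c(800, 390, 410, 800),
                  c(FALSE, TRUE, TRUE, FALSE))
  ed <- edit_artifacts(rr)
  expect_equal(ed$intervals, c(800, 800, 800))
  expect_false(any(ed$flags))
  expect_false(any(flag_artifacts(ed)$flags))
  # clean data pass through untouched
  clean <- rr_series(c(0, 800), c(800, 810))
  expect_identical(edit_artifacts(clean), clean)
})

test_that("unmatched flags are surfaced, not silently edited", {
  rr <- rr_series(c(0, 800, 1220), c(800, 420, 800),
                  c(FALSE, TRUE, FALSE))
  expect_warning(ed <- edit_artifacts(rr), "left flagged")
  expect_true(any(ed$flags))
  expect_equal(ed$intervals[ed$flags], 420)
})

test_that("editing conserves total recorded time across random corruptions", {
  for (seed in 1:5) {
    base <- rr_series(cumsum(c(0, rep(800, 39))), rep(800, 40))
    inj <- inject_artifacts(base, "missed_beat",
                            positions = c(5, 15, 25), seed = seed)
    ed <- edit_artifacts(flag_artifacts(inj$rr))
    expect_lte(abs(sum(ed$intervals) - sum(base$intervals)), 3)
  }
})

test_that("delimited round trips are exact and malformed input is named", {
  dir <- withr::local_tempdir()
  rr <- rr_series(c(0, 800), c(800, 801), c(FALSE, TRUE))
  p <- file.path(dir, "rr.tsv")
  write_rr(rr, p)
  back <- read_rr(p)
  expect_identical(back$intervals, rr$intervals)
  expect_identical(back$onsets, rr$onsets)
  expect_identical(back$flags, rr$flags)

  ev <- event_table(c("baseline", "trial"), c(0, 120000), c(120000, 30000))
  pe <- file.path(dir, "ev.tsv")
  write_events(ev, pe)
  expect_equal(as.data.frame(read_events(pe)), as.data.frame(ev))
  expect_error(event_table(c("a", "b"), c(0, 500), c(1000, 1000)),
               "overlapping events")

  pecg <- file.path(dir, "ecg.tsv")
  writeLines(c("time_s\tmv", "0\t0.0", "0.001\t0.5", "0.002\tbad"), pecg)
  expect_error(read_ecg_table(pecg), "row 3")
  writeLines(c("time_s\tmv", "0\t0.0", "0.002\t0.5", "0.001\t0.1"), pecg)
  expect_error(read_ecg_table(pecg), "unsorted input")

  ecg <- ecg_record(sin(seq(0, 10, by = 0.01)), 100)
  pw <- file.path(dir, "ecg2.tsv")
  write_ecg_table(ecg, pw)
  back <- read_ecg_table(pw)
  expect_equal(back$sampling_rate, 100, tolerance = 1e-6)
  expect_equal(back$samples, ecg$samples)
})
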