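make_rr <- function(v, t0 = 0) rr_series(t0 + cumsum(c(0, v[-length(v)])), v)

grid_hp <- function(values, grid_rate = 10, start_ms = 0) {
  structure(list(values = values, grid_rate = grid_rate,
                 start_ms = start_ms), class = "hp_series")
}

test_that("heart-period interpolation is linear with held endpoints", {
  rr <- make_rr(rep(800, 76))  # 60 s of constant 800 ms
  hp <- interpolate_heart_period(rr)
  expect_true(all(hp$values == 800))

  rr2 <- rr_series(c(0, 800), c(800, 1000))
  hp2 <- interpolate_heart_period(rr2)
  tt <- hp_times(hp2)
  expect_equal(hp2$values[tt == 400], 900)
  # held constant beyond the last beat onset
  expect_true(all(hp2$values[tt > 800] == 1000))
  # grid arithmetic: floor(span * rate) + 1 samples
  span_ms <- 1800
  expect_length(hp2$values, floor(span_ms / 1000 * 10) + 1)

  expect_error(interpolate_heart_period(rr_series(0, 800)), "too short")
})

test_that("the respiratory band filter meets its response invariants", {
  flt <- design_band_filter()
  h <- flt$coefficients
  expect_length(h, 241)
  expect_equal(h, rev(h))                       # linear phase
  expect_lt(filter_gain(flt, 0), 0.01)          # DC rejection
  g_center <- filter_gain(flt, 0.25)
  expect_gt(g_center, 0.95); expect_lt(g_center, 1.05)
  expect_lt(filter_gain(flt, 0.05), 10^(-20 / 20))
  expect_lt(filter_gain(flt, 0.50), 10^(-20 / 20))

  expect_error(design_band_filter(taps = 240), "invalid filter spec")
  expect_error(design_band_filter(band = c(0.12, 6)), "invalid filter spec")
})

test_that("band-filtered white noise carries the band's share of variance", {
  flt <- design_band_filter()
  set.seed(42)
  frac <- 2 * (0.40 - 0.12) / 10
  for (i in 1:3) {
    wn <- rnorm(20000)
    f <- stats::filter(wn, flt$coefficients, sides = 2)
    v <- stats::var(f[!is.na(f)])
    expect_lt(abs(v - frac) / frac, 0.20)
  }
})

test_that("ln band variance recovers the analytic sinusoid value", {
  flt <- design_band_filter()
  tt <- seq(0, 400000, by = 100)
  hp <- grid_hp(800 + 60 * sin(2 * pi * 0.25 * tt / 1000))
  ep <- event_table("e", 60000, 30000)
  out <- band_variance_ln(hp, flt, ep)
  expect_lt(abs(out$rsa_ln_ms2 - log(60^2 / 2)), 0.10)

  # same amplitude far below the band: at least 3 ln-units lower
  hp_lo <- grid_hp(800 + 60 * sin(2 * pi * 0.01 * tt / 1000))
  out_lo <- band_variance_ln(hp_lo, flt, ep)
  expect_lt(out_lo$rsa_ln_ms2, out$rsa_ln_ms2 - 3)

  expect_error(band_variance_ln(grid_hp(rep(800, 4001)), flt, ep),
               "degenerate epoch")
  expect_error(band_variance_ln(hp, flt, event_table("e", 0, 30000)),
               "epoch not covered")
})

test_that("amplitude scaling shifts RSA by 2 ln(c)", {
  flt <- design_band_filter()
  ep <- event_table(paste0("e", 1:4), 60000 + 30000 * (0:3), rep(30000, 4))
  rsa_for <- function(A) {
    s <- synth_rr(rr_sim_spec(rsa_amplitude = A, noise_sd = 0, seed = 9))
    hp <- interpolate_heart_period(s$rr)
    mean(band_variance_ln(hp, flt, ep)$rsa_ln_ms2)
  }
  r30 <- rsa_for(30); r60 <- rsa_for(60); r15 <- rsa_for(15)
  expect_lt(abs((r60 - r30) - 2 * log(2)), 0.1)
  expect_lt(abs((r15 - r30) - 2 * log(0.5)), 0.1)
})

test_that("end-to-end pipeline RSA matches the generator's expected value", {
  flt <- design_band_filter()
  ep <- event_table(paste0("e", 1:4), 60000 + 30000 * (0:3), rep(30000, 4))
  for (A in c(20, 40, 60)) {
    s <- synth_rr(rr_sim_spec(rsa_amplitude = A, noise_sd = 0, seed = 3))
    hp <- interpolate_heart_period(s$rr)
    est <- mean(band_variance_ln(hp, flt, ep)$rsa_ln_ms2)
    expect_lt(abs(est - s$truth$expected_rsa_ln), 0.15)
  }
})

test_that("condition averaging needs exactly four epochs and ignores order", {
  expect_equal(average_condition_rsa(c(5, 5, 5, 5)), 5)
  expect_equal(average_condition_rsa(c(4, 5, 6, 7)), 5.5)
  expect_equal(average_condition_rsa(c(7, 4, 6, 5)), 5.5)
  expect_error(average_condition_rsa(c(4, 5, 6)), "incomplete condition \\(3/4\\)")
})

test_that("reactivity is condition minus baseline with suppression negative", {
  expect_equal(reactivity(5, 5), 0)
  expect_equal(reactivity(4.5, 5), -0.5)
})

test_that("a full synthetic session yields the analytic reactivity", {
  ss <- synth_session(baseline_amplitude = 60, condition_amplitudes = 50,
                      seed = 2)
  res <- rsa_session(ss$rr, ss$events)
  expect_equal(nrow(res$conditions), 10)          # 8 conditions + 2 rests
  expect_true(all(res$conditions$n_epochs == 4))
  target <- 2 * log(50 / 60)
  expect_true(all(abs(res$reactivity$reactivity_ln_ms2 - target) < 0.15))
})

test_that("rest periods split into 30 s epochs and odd durations error", {
  ev <- event_table(c("baseline", "t1"), c(0, 120000), c(120000, 30000))
  sp <- split_epochs(ev)
  expect_equal(nrow(sp), 5)
  expect_true(all(sp$duration_ms == 30000))
  expect_error(split_epochs(event_table("x", 0, 45001)), "not a multiple")
})
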