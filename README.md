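# cardiovagal

Psychophysiological analysis of cardiac vagal tone and interoception, for
researchers studying autonomic correlates of social behaviour in clinical
groups (e.g. anorexia nervosa vs healthy controls). The package covers the
full computational chain of such a study:

* **ECG → R-R series**: Pan-Tompkins-style R-peak detection, intervals
  timed to the nearest ms, artifact flagging by a 300 ms
  successive-difference criterion, and editing by integer division (missed
  beats) or summation (spurious beats), with unresolved flags surfaced
  rather than silently edited.
* **R-R → RSA**: respiratory sinus arrhythmia estimated as
  ln Var[hp_band(t)], where hp_band is the heart-period series linearly
  interpolated to a 10 Hz grid and band-passed with a 241-tap FIR over
  0.12–0.40 Hz; computed per 30 s epoch, averaged over the four epochs of
  each condition, with reactivity = condition − baseline (negative =
  vagal suppression).
* **Heartbeat counting → IA**: interoceptive accuracy as the mean over
  four intervals (25/35/45/100 s) of `1 − |recorded − counted|/recorded`,
  clamped to [0, 1].
* **Cohort statistics**: pooled t-tests; ANCOVA with Type III F, partial
  η² and adjusted marginal means; 2×2×2×group mixed ANOVA with Tukey
  post-hocs; Shapiro-Wilk-gated Spearman (exactly Pearson on mid-ranks);
  Fisher r-to-z comparison of independent correlations,
  z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)); Bonferroni
  thresholds; reciprocal normalization of comfort distances; standardized
  simple regression (R² = b², F = t²); Mahalanobis outlier screening.
* **Synthetic data**: seeded generators with analytic ground truth for
  every stage — RR series with known respiratory-band variance, ECG with
  planted R-peaks, artifact injection with truth logs, counting behaviour
  with a tunable accuracy, and two-group cohorts with planted
  correlation/regression structure.

A 24-patient clinical table (age, onset age, illness duration, IA,
resting RSA) ships as a bundled fixture and drives the worked examples.

## Worked example

```r
library(cardiovagal)

t2 <- load_table2()
spearman_cor(t2$resting_rsa, t2$age_of_onset)
#> Spearman correlation: r = -0.159, n = 24 (df = 22), t = -0.754, p = 0.4589 (one-sided 0.2295)

pearson_cor(t2$ia, t2$resting_rsa)
#> Pearson correlation: r = -0.382, n = 24 (df = 22), t = -1.936, p = 0.0658 (one-sided 0.0329)

fisher_rz_compare(0.40, 23, -0.39, 24)
#> Fisher r-to-z: r1 = 0.400 (n = 23) vs r2 = -0.390 (n = 24): z = 2.674, p = 0.0075
```

The Spearman between resting RSA and onset age is −0.16: in these patients
the age at which the illness began carries no reliable signal about adult
vagal tone. The Pearson between interoceptive accuracy and resting RSA is
−0.38: patients with *better* heartbeat perception have *lower* vagal
tone. Comparing that against a control-group coefficient of +0.40 gives
z = 2.67 (p ≈ 0.008): the two groups associate interoception and vagal
tone in opposite directions.

A fully synthetic session exercises the RSA chain end to end:

```r
ss  <- synth_session(baseline_amplitude = 60, condition_amplitudes = 50, seed = 2)
res <- rsa_session(ss$rr, ss$events)
head(res$reactivity[, c("label", "condition_rsa", "baseline_rsa", "reactivity_ln_ms2")], 3)
#>             label condition_rsa baseline_rsa reactivity_ln_ms2
#> 1   thin.far.gaze      6.873432      7.22939        -0.3559573
#> 2 thin.far.nogaze      6.875075      7.22939        -0.3543146
#> 3  thin.near.gaze      6.871020      7.22939        -0.3583693
```

Dropping the respiratory amplitude from 60 to 50 ms should change RSA by
2·ln(50/60) = −0.365; the pipeline reports −0.354 to −0.358 per
condition, the small gap reflecting finite-epoch variance estimation.

A thin CLI wraps the same functions
(`exec/cardiovagal <preprocess|rsa|ia|analyze|simulate|table2> ...`), and
`run_simulate()` emits a complete on-disk dataset in the same formats the
readers consume, so end-to-end runs need no real recordings.

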