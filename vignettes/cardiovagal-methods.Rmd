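---
title: "Methods: RSA estimation, interoceptive accuracy, and the inferential battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RSA estimation, interoceptive accuracy, and the inferential battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiovagal)
```

`cardiovagal` implements the computational chain of a resting/reactive
cardiac vagal tone study: from raw ECG to respiratory sinus arrhythmia
(RSA) estimates, from heartbeat-counting behaviour to an interoceptive
accuracy (IA) score, and from per-subject cohort tables to the group-level
inferential battery. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices the package makes where
the procedure left genuine freedom.

## From ECG to an edited R-R series

**R-peak detection.** `detect_r_peaks()` is a Pan-Tompkins-style
energy detector: a 5--15 Hz Butterworth band-pass emphasizes the QRS
complex, the squared derivative is smoothed over 120 ms, and supra-threshold
regions (25% of the maximum energy) become beat candidates, resolved
greedily under a refractory period (`min_separation`, default 300 ms).
Each candidate is then re-localized to the maximum absolute deflection of
the raw trace after a light 15 ms moving-average smoothing. The smoothing
matters: with sample-level noise at 5--10% of the R amplitude, the raw
argmax jitters by several samples, while the smoothed argmax stays on the
R apex; on synthetic records with planted peaks the detector recovers
more than 99% of beats within one sample at those noise levels. The
detector assumes an upright dominant R deflection and a single lead;
morphological beat classification is out of scope.

**Interval construction.** Intervals are successive peak differences
rounded to the nearest ms; onsets are rebuilt from the cumulative rounded
intervals so the series is internally exact. All internal times are
integer milliseconds; other sampling rates are converted at read time.

**Artifact flagging.** The criterion is a successive-difference threshold
(default 300 ms) on adjacent intervals. A threshold exceedance marks a
*transition*, not an interval, so the package must decide which of the two
intervals is aberrant: it attributes each exceeding transition to the
member lying farther from the local median (a window of 21 intervals),
breaking ties toward the later interval, since an artifact typically
follows good data. This reproduces the intuitive readings of the
canonical cases — in `[800, 1600, 800]` only the 1600 is flagged although
both of its transitions exceed the threshold; in `[800, 400, 400, 800]`
the first 400 and the final 800 are flagged, one per exceeding
transition. Values are never modified by flagging, and flagging is
idempotent.

**Editing.** `edit_artifacts()` resolves flagged runs against the local
median of unflagged neighbours with a 20% matching tolerance:

* *integer division* — a single long interval consistent with `k` missed
  beats (value/(k+1) within 20% of the median) becomes `k+1` integer
  intervals preserving the sum exactly;
* *summation* — a run whose sum is within 20% of the median becomes one
  interval equal to that sum;
* if neither fits, the run is extended by at most one adjacent unflagged
  interval and re-tried as a summation. This covers a spurious beat that
  splits an interval asymmetrically, where only the shorter fragment
  triggers the flag.

Anything still unmatched is left flagged and surfaced with a warning —
the in-code surrogate for the visual inspection step of a human editor.
Both edit patterns conserve total recorded time exactly, a property the
tests verify on randomly corrupted series.

## The RSA estimator

RSA is estimated as the natural log of heart-period variance in the
spontaneous-respiration band, by the four-step time-domain chain:

1. linear interpolation of the R-R tachogram (interval value against beat
   onset time) onto a 10 Hz grid, endpoints held constant;
2. a 241-tap linear-phase FIR band-pass, 0.12--0.40 Hz, windowed-sinc
   (Hamming) design;
3. population variance (divide by *n*) of the filtered signal within each
   30 s epoch;
4. natural logarithm, giving ln(ms²).

The FIR design method is validated by response invariants rather than
coefficient identity with any particular tool: gain at the band centre
within 1% of unity, DC gain below 0.01, at least 20 dB attenuation at
0.05 Hz and 0.50 Hz, and exact coefficient symmetry. On white noise the
filter passes the band's share of variance (Parseval check, within 20%).

**Filter-then-epoch.** A 241-tap filter at 10 Hz spans 24 s — nearly a
whole epoch — so the filter is applied to the whole record once and
epochs are cut from the filtered signal afterwards. Filtering each epoch
separately would put catastrophic edge transients inside every epoch. The
first and last 12 s of a record are not covered by the filter support and
are reported as `NA`; an epoch touching them raises "epoch not covered"
rather than returning a biased value. The synthetic session generator
therefore records 15 s of unlabelled rest before the baseline and after
the recovery, as a real acquisition would.

**Variance convention.** The population variance is used within epochs; at
300 samples per epoch the ln of the variance is insensitive to the *n* vs
*n − 1* choice, but it is fixed and documented here.

**Known bias of linear tachogram interpolation.** The tachogram samples
the heart-period process at the beat rate (≈1.25 Hz at a resting 800 ms
heart period). Linear interpolation acts as a triangular reconstruction
filter with amplitude response sinc²(*f·T*), so a respiratory oscillation
at *f* = 0.25 Hz is attenuated by sinc²(0.2) ≈ 0.875 in amplitude, i.e.
4·ln sinc(0.2) ≈ −0.27 ln-units in the reported RSA. The package measures
exactly this on synthetic records (−0.26 to −0.27 across amplitudes 20,
40, 60 ms). The bias is a property of the estimator class, not of the
implementation: it cancels in every *within-subject* contrast computed at
a stable heart rate — condition averages, reactivity scores, amplitude
ratios (doubling the amplitude shifts RSA by 2·ln 2 regardless) — and
shrinks only at implausibly fast resting heart rates. For this reason the
synthetic generator's ground truth reports both the in-band variance of
the generating process (A²/2 plus the in-band noise share) and
`expected_rsa_ln`, the value the estimator is expected to produce with the
attenuation included; end-to-end validation targets the latter to within
±0.15 ln-units and lands within ≈0.01 of the analytic prediction.

**Averaging and reactivity.** Condition RSA is the arithmetic mean of
exactly four 30 s epochs (the count is enforced; the error names the
deficit), as are the 2-min baseline and recovery rests. Reactivity is
condition minus baseline — negative values mean vagal suppression. The
baseline is always the session's initial rest; the post-task rest is kept
as "recovery" and never subtracted.

## Interoceptive accuracy

Each counting interval scores `1 − |recorded − counted| / recorded`; the
IA score is the mean over the task's four intervals (25, 35, 45, 100 s).
The formula goes negative if a participant counts more than twice the
recorded beats; because the score is defined on [0, 1], such values are
clamped to zero *with a warning* rather than silently discarded — whether
real protocols ever observe such over-counting is unknowable from the
score definition alone, so the package records the event. Recorded
reference counts come from the R-R series on a half-open window
[onset, onset + duration), a convention fixed here to make boundary beats
unambiguous.

## The inferential battery

* **Group comparisons** use the pooled-variance two-sample t
  (df = n₁ + n₂ − 2), with an explicit "degenerate samples" error when
  the pooled variance is zero.
* **Normality gating** uses Shapiro-Wilk; non-normal variables are
  analysed with Spearman correlations, defined here *exactly* as Pearson
  on mid-ranks (average ranks for ties). P-values use the t transform;
  both tails are reported and the two-sided value is the default. (On the
  bundled cohort table the one-sided tails match the published p-values,
  which suggests the original analyses were one-tailed; the package
  reports both rather than silently matching.)
* **Fisher r-to-z** compares two independent correlations:
  z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)), two-sided normal p.
* **ANCOVA** is a general linear model with sum-to-zero group contrasts;
  each term gets a marginal (Type III) F and partial eta squared
  SS_effect/(SS_effect + SS_error). Eta squared is reported as *partial*
  — the convention of the commercial packages this battery mirrors.
  Adjusted marginal means are model predictions at user-specified
  covariate values (grand means by default), with delta-method standard
  errors; they match `emmeans` to 1e-8 in the cross-check tests.
  Constant covariates carry no information and are dropped with a
  message, which reduces the model to a one-way ANOVA exactly. The
  repeated-measures use (baseline vs recovery with covariates) is run on
  subject means for the between-group effect.
* **Mixed ANOVA** (2×2×2 within × group) uses univariate error strata;
  two-level factors need no sphericity correction. Effects whose sum of
  squares is numerically zero relative to the design's total are reported
  as F = 0, p = 1 rather than as an indeterminate ratio of rounding
  residue. Tukey post-hocs use the studentized-range distribution with
  the error stratum's df (Tukey-Kramer for unequal cells).
* **Comfort distances** are reciprocal-normalized (x → 1/x) before the
  ANOVA, with summaries reported on the raw cm scale.
* **Simple regression** is standardized, so b equals the Pearson r and
  R² = b², F = t² hold as identities (asserted to 1e-10 in tests).
* **Multivariate outlier screening** is a labelled stand-in: squared
  Mahalanobis distance against the chi-square quantile (default
  α = 0.001), since the original screening criterion is not recoverable.

## The synthetic generators and what they do not show

All generators are pure functions of an explicit seed; they save and
restore the caller's RNG state, and every generated object travels with
its ground truth so no test reads truth from the code under test.

* `synth_rr()` uses a sinusoid-plus-noise tachogram,
  RRₖ = mean + A·sin(2πf tₖ) + εₖ, chosen over integral-pulse
  frequency modulation for the analytic tractability of its in-band
  variance; IPFM is a possible extension. Defaults describe a resting
  adult: 800 ms mean heart period (75 bpm), A = 40 ms at 0.25 Hz
  (15 breaths/min), 5 ms beat noise, 5-minute records.
* `synth_ecg()` plants a Ricker-wavelet QRS (1 mV, 80 ms support) at each
  beat; it validates that the template is narrower than the shortest
  interval. It has no P/T waves or ectopy, so detector validation here
  shows localization accuracy, not morphological robustness.
* `inject_artifacts()` produces the two canonical artifact types with a
  truth log; spurious-beat splits draw from the central 20--80% of the
  interval so no sub-millisecond fragments arise.
* `synth_counting()` maps an accuracy parameter to counts via
  counted = round(recorded·(1 − (1 − accuracy)·u)), u ~ U(0, 1), making
  the expected IA score increase in the parameter.
* `synth_cohort()` plants a bivariate-normal IA-RSA correlation per group
  (+0.4 controls, −0.4 patients by default, n = 24 per group, matching
  the published group moments: RSA 5.3 vs 3.7 ln(ms²), SD 1.6; IA 0.41
  vs 0.53, SD 0.17) and a linear comfort-distance dependence on resting
  RSA in the control group only (−9 cm per ln-unit ≈ a standardized slope
  of −0.47 at these SDs). At these planted values the per-group sign of
  the correlation is recovered in ≈96--98% of replicates and the Fisher z
  is positive in >99%; the z-test rejects at α = 0.05 in ≈77--80% —
  consistent with the analytic power of the transform at |ρ| = 0.4,
  n = 24.
* `synth_reactivity()` plants a single-cell, single-group offset for the
  four-way interaction; the default of 1.1 ln-units (between-subject SD
  0.6, residual SD 0.4) is sized so the interaction is detected in ≈88%
  of replicates at n = 24 per group — deliberately larger than the
  published effect, which at its own size would sit near 50% power.

These generators emulate band structure, artifact patterns, counting
behaviour and cohort correlation geometry. They do not emulate
non-stationary respiration, heart-rate trends, ectopy, missing cells, or
measurement error in the covariates; passing tests therefore demonstrate
correctness of the computational chain under the stated model, not
robustness to every property of real recordings.

## Problem sizes and determinism

The validation suite uses 5-minute synthetic records for estimator
properties, 120 s records for detector benchmarks, 200 replicates for the
mixed-ANOVA power property and the null-slope calibration, and 500
replicates for the correlation-dissociation recovery; these sizes give
stable proportions (binomial SE ≤ 2%) while keeping a full run in the
tens of seconds. Every pipeline entry point is deterministic given its
configuration and seed; identical runs produce byte-identical output
tables, and the run log records every override, clamp, surfaced artifact
flag and dropped covariate so that silent data editing is impossible.

## Known limitations

* The tachogram-interpolation attenuation described above biases
  *absolute* RSA levels downward by ≈0.27 ln-units at typical resting
  rates; comparisons across heart-rate regimes inherit a differential
  version of this bias that the estimator cannot remove.
* The artifact editor resolves only the two canonical patterns (plus
  their one-neighbour extension); pathological runs are surfaced, not
  guessed.
* The Spearman p-value uses the t approximation, adequate at n ≥ 10 but
  approximate for very small samples.
* IA clamping at zero makes the score distribution slightly non-normal
  near the floor; the battery's normality gate exists for exactly this
  kind of case.
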