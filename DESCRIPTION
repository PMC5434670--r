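Package: cardiovagal
Title: Respiratory Sinus Arrhythmia, Interoceptive Accuracy, and
    Autonomic Group Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for psychophysiological studies of cardiac vagal tone
    and interoception. Detects R-peaks in raw ECG, builds and edits R-R
    interval series with a successive-difference artifact criterion,
    estimates respiratory sinus arrhythmia (RSA) as the natural log of
    band-passed (0.12-0.40 Hz) heart-period variance via linear
    interpolation to a 10 Hz grid and a 241-tap FIR filter, scores the
    heartbeat-counting (mental tracking) interoceptive-accuracy task,
    and runs the accompanying inferential battery: pooled t-tests,
    ANCOVA with adjusted marginal means, mixed within-between ANOVA
    with Tukey post-hocs, Shapiro-Wilk gated Spearman/Pearson
    correlations, Fisher r-to-z comparison of independent correlations,
    and simple standardized regression. Seeded synthetic-data
    generators with analytic ground truth support validation of every
    stage. A bundled clinical cohort table ships as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    withr,
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
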