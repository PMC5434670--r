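test_that("pooled t-test matches the textbook formula", {
  set.seed(11)
  x <- rnorm(14, 1, 2); y <- rnorm(20, 0, 2)
  res <- independent_t_test(x, y)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, n1 + n2 - 2)
  expect_equal(res$p, 2 * pt(-abs(t_hand), n1 + n2 - 2), tolerance = 1e-10)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(independent_t_test(c(0, 0), c(1, 1)), "degenerate samples")
})

test_that("Shapiro-Wilk gates normal vs skewed samples", {
  z <- qnorm(ppoints(50))
  expect_gt(shapiro_wilk(z)$W, 0.99)
  expect_lt(shapiro_wilk(c(1, 1, 1, 1, 100))$p, 0.05)
  expect_error(shapiro_wilk(c(2, 2)), "too few")
  expect_error(shapiro_wilk(rep(3, 10)), "degenerate")
})

test_that("Spearman is exactly Pearson on mid-ranks", {
  set.seed(21)
  for (i in 1:20) {
    x <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- x + rnorm(30, 0, 2)
    expect_identical(spearman_cor(x, y)$r,
                     pearson_cor(midrank(x), midrank(y))$r)
  }
  # invariant under strictly monotone transforms
  x <- rexp(25); y <- rnorm(25)
  expect_equal(spearman_cor(exp(x), y)$r, spearman_cor(x, y)$r)
  expect_equal(spearman_cor(x, y^3)$r, spearman_cor(x, y)$r)

  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1)
  expect_error(pearson_cor(rep(1, 5), 1:5), "degenerate")
  res <- pearson_cor(rnorm(20), rnorm(20))
  expect_equal(res$df, res$n - 2L)
  expect_true(abs(res$r) <= 1)
})

test_that("Fisher r-to-z follows the closed form and is antisymmetric", {
  z <- fisher_rz_compare(0.5, 20, -0.5, 20)
  expect_equal(z$z, 2 * atanh(0.5) / sqrt(2 / 17), tolerance = 1e-12)
  expect_equal(round(z$z, 2), 3.20)

  expect_equal(fisher_rz_compare(0.3, 30, 0.6, 40)$z,
               -fisher_rz_compare(0.6, 40, 0.3, 30)$z)
  expect_equal(fisher_rz_compare(0.4, 25, 0.4, 25)$z, 0)
  expect_error(fisher_rz_compare(1, 20, 0, 20), "transform undefined")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("ANCOVA reduces to one-way ANOVA under constant covariates", {
  set.seed(31)
  d <- data.frame(y = rnorm(40) + rep(c(0, 0.8), each = 20),
                  group = rep(c("A", "B"), each = 20), cst = 7)
  res <- suppressMessages(ancova(d, "y", "group", "cst"))
  f_aov <- summary(aov(y ~ group, d))[[1]]$`F value`[1]
  expect_lt(abs(res$effects$F[res$effects$term == "group"] - f_aov), 1e-9)
})

test_that("adjusted marginal means agree with an independent GLM route", {
  skip_if_not_installed("emmeans")
  set.seed(32)
  d <- data.frame(y = rnorm(48), group = rep(c("A", "B"), each = 24),
                  age = rnorm(48, 23, 5), bmi = rnorm(48, 19, 2))
  d$y <- d$y + 0.1 * d$age + ifelse(d$group == "B", 1, 0)
  res <- ancova(d, "y", "group", c("age", "bmi"))
  fit <- lm(y ~ group + age + bmi, d)
  em <- as.data.frame(emmeans::emmeans(fit, "group"))
  expect_equal(res$emmeans$mean, em$emmean, tolerance = 1e-8)
  expect_equal(res$emmeans$se, em$SE, tolerance = 1e-8)
})

test_that("ANCOVA recovers a planted adjusted group difference", {
  # balanced covariates identical across groups: adjusted = raw means
  x <- rep(seq(-2, 2, length.out = 10), 2)
  d <- data.frame(group = rep(c("A", "B"), each = 10), age = x)
  d$y <- ifelse(d$group == "B", 1.5, 0) + 0.5 * d$age
  # exact-fit construction: lm legitimately warns about a perfect fit
  res <- suppressWarnings(ancova(d, "y", "group", "age"))
  raw <- tapply(d$y, d$group, mean)
  expect_equal(res$emmeans$mean, as.numeric(raw), tolerance = 1e-10)
  expect_equal(diff(res$emmeans$mean), 1.5, tolerance = 1e-10)

  # noisy planted gap with a covariate effect: recovered within 2 SE
  set.seed(33)
  d2 <- data.frame(group = rep(c("A", "B"), each = 30),
                   age = rnorm(60, 25, 4))
  d2$y <- 0.3 * d2$age + ifelse(d2$group == "B", 0.9, 0) + rnorm(60, 0, 0.8)
  r2 <- ancova(d2, "y", "group", "age")
  gap <- diff(r2$emmeans$mean)
  se_gap <- sqrt(sum(r2$emmeans$se^2))
  expect_lt(abs(gap - 0.9), 2 * se_gap)

  d3 <- data.frame(y = rnorm(20), group = rep(c("A", "B"), 10),
                   a = 1:20, b = 2 * (1:20))
  expect_error(ancova(d3, "y", "group", c("a", "b")), "rank-deficient")
})

test_that("mixed ANOVA handles null data and relabeling invariance", {
  grid <- expand.grid(bmi = c("thin", "fat"), distance = c("far", "near"),
                      gaze = c("gaze", "nogaze"),
                      stringsAsFactors = FALSE)
  subj <- paste0("s", 1:12)
  d <- do.call(rbind, lapply(seq_along(subj), function(i) {
    cbind(data.frame(subject = subj[i],
                     group = ifelse(i <= 6, "HC", "AN"),
                     stringsAsFactors = FALSE), grid)
  }))
  # response varies by subject only: every within-effect F must be exactly 0
  set.seed(61)
  d$y <- rep(rnorm(12, 5, 1), each = 8)
  ma <- mixed_anova(d, "y", c("bmi", "distance", "gaze"), "group", "subject")
  within_rows <- grepl("bmi|distance|gaze", ma$effects$term)
  expect_true(all(ma$effects$F[within_rows] == 0))

  # invariance to subject relabeling and row order
  sr <- synth_reactivity(n_per_group = 8, seed = 6)
  m1 <- mixed_anova(sr$data, "reactivity", c("bmi", "distance", "gaze"),
                    "group", "subject")
  perm <- sr$data[sample(nrow(sr$data)), ]
  perm$subject <- paste0("x_", perm$subject)
  m2 <- mixed_anova(perm, "reactivity", c("bmi", "distance", "gaze"),
                    "group", "subject")
  expect_equal(m1$effects$F[order(m1$effects$term)],
               m2$effects$F[order(m2$effects$term)], tolerance = 1e-10)

  d_bad <- d[-1, ]
  expect_error(mixed_anova(d_bad, "y", c("bmi", "distance", "gaze"),
                           "group", "subject"), "incomplete design")
})

test_that("a planted four-way interaction is detected with adequate power", {
  hits <- 0L
  for (i in 1:200) {
    sr <- synth_reactivity(seed = i)
    ma <- mixed_anova(sr$data, "reactivity", c("bmi", "distance", "gaze"),
                      "group", "subject")
    p <- ma$effects$p[ma$effects$term == "group:bmi:distance:gaze"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.80)
})

test_that("Tukey HSD agrees with direct studentized-range evaluation", {
  set.seed(41)
  vals <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  cells <- rep(c("a", "b", "c"), each = 8)
  res <- tukey_hsd_oneway(vals, cells)

  means <- tapply(vals, cells, mean)
  mse <- sum(tapply(vals, cells, function(v) sum((v - mean(v))^2))) / 21
  for (i in seq_len(nrow(res))) {
    q <- abs(means[res$cell_a[i]] - means[res$cell_b[i]]) / sqrt(mse / 8)
    expect_equal(res$q[i], unname(q), tolerance = 1e-10)
    expect_equal(res$p[i],
                 ptukey(unname(q), 3, 21, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # cross-check against the base aov post-hoc route
  th <- TukeyHSD(aov(vals ~ factor(cells)))$`factor(cells)`
  expect_equal(sort(res$p), sort(unname(th[, "p adj"])), tolerance = 1e-8)
})

test_that("reciprocal normalization is 1/x on positive distances", {
  expect_equal(reciprocal_normalize(100), 0.01)
  d <- c(50, 80, 120, 200)
  expect_true(all(diff(reciprocal_normalize(d)) < 0))
  expect_error(reciprocal_normalize(0), "invalid distance")
})

test_that("standardized regression satisfies its algebraic identities", {
  set.seed(51)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  res <- simple_regression(y, x)
  expect_equal(res$r_squared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(res$r_squared, res$b^2, tolerance = 1e-12)
  expect_equal(res$F, res$t^2, tolerance = 1e-10)

  ident <- suppressWarnings(simple_regression(1:10, 1:10))
  expect_equal(ident$b, 1); expect_equal(ident$r_squared, 1)
  expect_error(simple_regression(rnorm(10), rep(2, 10)),
               "degenerate predictor")
})

test_that("Mahalanobis screening flags constructed outliers and calibrates", {
  x <- rbind(matrix(rnorm(100, sd = 0.2), ncol = 2) + 1, c(30, -30))
  res <- mahalanobis_outliers(x, alpha = 0.001)
  expect_equal(res$flagged, 51L)

  # affine invariance of the distances
  A <- matrix(c(2, 0.5, -1, 3), 2)
  y <- x %*% A + matrix(c(5, -2), nrow(x), 2, byrow = TRUE)
  expect_equal(mahalanobis_outliers(y, 0.001)$d2, res$d2, tolerance = 1e-8)

  set.seed(3)
  z <- matrix(rnorm(2000), ncol = 2)
  expect_lte(length(mahalanobis_outliers(z, 0.001)$flagged), 5)
  expect_error(mahalanobis_outliers(cbind(1:10, 2 * (1:10))),
               "singular covariance")
})
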