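#' Independent-samples pooled-variance t-test
#'
#' Classical two-sample t with pooled variance and df = n1 + n2 - 2, the
#' form used for group comparisons of demographics and questionnaire
#' scores.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param two_sided Report the two-sided p (default `TRUE`).
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
independent_t_test <- function(x, y, two_sided = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("degenerate samples: zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  p <- unname(ht$p.value)
  if (!two_sided) p <- p / 2
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       mean_x = mean(x), mean_y = mean(y))
}

#' Shapiro-Wilk normality test
#'
#' Used as the gate for choosing rank-based (Spearman) over parametric
#' correlations.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("too few observations for Shapiro-Wilk (n < 3)")
  if (length(x) > 5000) stop("Shapiro-Wilk limited to n <= 5000")
  if (stats::var(x) == 0) stop("degenerate: constant sample")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mid-ranks (average ranks for ties)
#' @param x Numeric vector.
#' @return Rank vector with tied observations given their average rank.
#' @export
midrank <- function(x) rank(x, ties.method = "average")

cor_result <- function(method, r, n) {
  df <- n - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  p_two <- 2 * stats::pt(-abs(tstat), df)
  structure(list(method = method, r = r, n = n, df = df, statistic = tstat,
                 p = p_two, p_one_sided = p_two / 2),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, n = %d (df = %d), t = %.3f, p = %.4f (one-sided %.4f)\n",
              x$method, x$r, x$n, x$df, x$statistic, x$p, x$p_one_sided))
  invisible(x)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate: zero variance")
  list(x = x, y = y)
}

#' Pearson and Spearman correlations
#'
#' `pearson_cor` is the product-moment correlation with a two-sided p from
#' the t transform (one-sided tail also reported). `spearman_cor` is
#' defined as the Pearson correlation of mid-ranks (average ranks for
#' ties), with the same t-approximation p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-constant).
#' @return A `correlation_result`: `method`, `r`, `n`, `df`, `statistic`,
#'   `p` (two-sided), `p_one_sided`.
#' @export
pearson_cor <- function(x, y) {
  d <- check_cor_input(x, y)
  cor_result("Pearson", stats::cor(d$x, d$y), length(d$x))
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  d <- check_cor_input(x, y)
  cor_result("Spearman", stats::cor(midrank(d$x), midrank(d$y)),
             length(d$x))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests equality of two correlations from independent samples using the
#' variance-stabilizing transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return An object of class `z_comparison`: `r1`, `n1`, `r2`, `n2`, `z`,
#'   `p`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("transform undefined for |r| = 1")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "z_comparison")
}

#' @export
print.z_comparison <- function(x, ...) {
  cat(sprintf("Fisher r-to-z: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): z = %.3f, p = %.4f\n",
              x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#' @param alpha Family-wise alpha.
#' @param m Number of planned tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Between-subjects ANCOVA with adjusted marginal means
#'
#' General linear model `response ~ group + covariates` with sum-to-zero
#' group contrasts. Reports a marginal (Type III) F test, partial eta
#' squared `SS_effect / (SS_effect + SS_error)` for the group factor and
#' each covariate, and group means adjusted to specified covariate values
#' (covariate grand means by default). Covariates with zero variance carry
#' no information and are dropped with a message, which reduces the model
#' to a one-way ANOVA when all are constant.
#'
#' @param data data.frame containing the variables.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping factor column (>= 2 levels).
#' @param covariates Character vector of covariate column names.
#' @param at Named numeric vector of covariate evaluation values for the
#'   adjusted means (default: grand means).
#' @return An object of class `anova_table`: `effects` data.frame (`term`,
#'   `F`, `df1`, `df2`, `p`, `eta2_partial`), `emmeans` data.frame
#'   (`group`, `mean`, `se`), `at` (covariate values used), `model` (the
#'   fitted `lm`).
#' @export
ancova <- function(data, response, group, covariates = character(0),
                   at = NULL) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  keep <- covariates[vapply(covariates, function(cv)
    stats::var(data[[cv]], na.rm = TRUE) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped))
    message(sprintf("dropping constant covariate(s): %s",
                    paste(dropped, collapse = ", ")))
  covariates <- keep

  df <- data.frame(.y = data[[response]], .g = g, check.names = FALSE)
  for (cv in covariates) df[[cv]] <- data[[cv]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= nlevels(g) + length(covariates))
    stop("too few observations for the model")

  rhs <- paste(c(".g", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df,
                   contrasts = list(.g = "contr.sum"))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design matrix")

  ss_res <- sum(stats::residuals(fit)^2)
  df_res <- fit$df.residual
  dr <- stats::drop1(fit, test = "F")
  terms <- rownames(dr)[-1L]
  eff <- data.frame(term = sub("^\\.g$", group, terms),
                    F = dr$`F value`[-1L],
                    df1 = dr$Df[-1L], df2 = df_res,
                    p = dr$`Pr(>F)`[-1L],
                    stringsAsFactors = FALSE)
  eff$eta2_partial <- (eff$F * eff$df1) / (eff$F * eff$df1 + df_res)

  # adjusted marginal means at the requested covariate values
  if (is.null(at)) {
    at <- vapply(covariates, function(cv) mean(df[[cv]]), numeric(1))
  } else {
    at <- at[covariates]
  }
  grid <- data.frame(.g = factor(levels(g), levels = levels(g)))
  for (cv in covariates) grid[[cv]] <- unname(at[cv])
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid,
                           contrasts.arg = list(.g = "contr.sum"))
  est <- as.numeric(X %*% stats::coef(fit))
  se <- sqrt(diag(X %*% stats::vcov(fit) %*% t(X)))
  emm <- data.frame(group = levels(g), mean = est, se = se,
                    stringsAsFactors = FALSE)

  structure(list(effects = eff, emmeans = emm, at = at, model = fit),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Effects:\n")
  print(x$effects, row.names = FALSE, digits = 4)
  if (!is.null(x$emmeans)) {
    cat("\nAdjusted marginal means:\n")
    print(x$emmeans, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Mixed within-between ANOVA (2 x 2 x ... within, one between factor)
#'
#' Univariate repeated-measures ANOVA via `aov` with the within-subject
#' error strata `Error(subject/(w1*w2*...))`. All main effects and
#' interactions up to the full within-by-between term are reported with F,
#' degrees of freedom, p, and partial eta squared computed against the
#' error sum of squares of the effect's own stratum. Two-level within
#' factors need no sphericity correction.
#'
#' @param data Long-format data.frame: one row per subject x within-cell.
#' @param response Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param between Name of the between-subjects factor column.
#' @param subject Name of the subject identifier column.
#' @return An `anova_table` with the `effects` data.frame.
#' @export
mixed_anova <- function(data, response, within, between, subject) {
  df <- data
  df$.y <- df[[response]]
  df$.s <- factor(df[[subject]])
  df$.b <- factor(df[[between]])
  for (k in seq_along(within)) df[[within[k]]] <- factor(df[[within[k]]])

  # completeness: every subject must have every within-cell exactly once
  cells <- interaction(df[within], drop = FALSE)
  tab <- table(df$.s, cells)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("incomplete design: subject %s, cell %s",
                 rownames(tab)[bad[1L]], colnames(tab)[bad[2L]]))
  }

  wterm <- paste(within, collapse = "*")
  f <- stats::as.formula(paste0(".y ~ .b*", wterm,
                                " + Error(.s/(", wterm, "))"))
  fit <- stats::aov(f, data = df)
  sm <- summary(fit)

  total_ss <- sum(vapply(sm, function(st) sum(st[[1L]]$`Sum Sq`),
                         numeric(1)))
  eff <- NULL
  for (stratum in sm) {
    s <- stratum[[1L]]
    rn <- trimws(rownames(s))
    resid_row <- rn == "Residuals"
    if (!any(resid_row)) next
    ss_err <- s$`Sum Sq`[resid_row]
    df_err <- s$Df[resid_row]
    keep <- !resid_row
    if (!any(keep)) next
    blk <- data.frame(
      term = gsub("\\.b", between, rn[keep]),
      F = s$`F value`[keep],
      df1 = s$Df[keep], df2 = df_err,
      p = s$`Pr(>F)`[keep],
      eta2_partial = s$`Sum Sq`[keep] / (s$`Sum Sq`[keep] + ss_err),
      stringsAsFactors = FALSE)
    # a zero-variance effect is no effect, not an indeterminate ratio of
    # rounding residue; judge "zero" relative to the design's total SS
    tiny <- 1e-12 * max(total_ss, 1e-300)
    null_eff <- (s$`Sum Sq`[keep] <= tiny) &
      (!is.finite(blk$F) | ss_err <= tiny)
    blk$F[null_eff] <- 0
    blk$p[null_eff] <- 1
    blk$eta2_partial[null_eff] <- 0
    eff <- rbind(eff, blk)
  }
  rownames(eff) <- NULL
  structure(list(effects = eff, emmeans = NULL, model = fit),
            class = "anova_table")
}

#' Tukey HSD pairwise comparisons from cell summaries
#'
#' Studentized-range test over all cell pairs:
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` compared to the
#' studentized-range distribution with k cells and the error df
#' (Tukey-Kramer form for unequal cell sizes).
#'
#' @param means Named numeric vector of cell means.
#' @param n Cell sizes (scalar or one per cell).
#' @param mse Error mean square.
#' @param df Error degrees of freedom.
#' @return data.frame with one row per pair: `cell_a`, `cell_b`, `diff`,
#'   `q`, `p`.
#' @export
tukey_hsd <- function(means, n, mse, df) {
  k <- length(means)
  if (k < 2) stop("need at least 2 cells")
  if (length(n) == 1L) n <- rep(n, k)
  labs <- names(means)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d <- means[i] - means[j]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(d) / se
    out <- rbind(out, data.frame(
      cell_a = labs[i], cell_b = labs[j], diff = unname(d), q = unname(q),
      p = stats::ptukey(q, k, df, lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Tukey HSD from raw one-way cell data
#'
#' Convenience wrapper computing cell means, the pooled error mean square
#' and its df from raw values, then delegating to [tukey_hsd()].
#'
#' @param values Numeric response vector.
#' @param cells Factor (or coercible) of cell labels.
#' @return As [tukey_hsd()].
#' @export
tukey_hsd_oneway <- function(values, cells) {
  cells <- factor(cells)
  means <- tapply(values, cells, mean)
  ns <- tapply(values, cells, length)
  ss_err <- sum(tapply(values, cells, function(v) sum((v - mean(v))^2)))
  df_err <- length(values) - nlevels(cells)
  tukey_hsd(means, as.numeric(ns), ss_err / df_err, df_err)
}

#' Reciprocal normalization of comfort distances
#'
#' Distance ratings are normalized as `1/x` before entering the ANOVA;
#' cell summaries are reported back on the raw cm scale. Strictly
#' decreasing in distance.
#'
#' @param distance_cm Distances in cm (> 0).
#' @return `1/distance_cm`.
#' @export
reciprocal_normalize <- function(distance_cm) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0))
    stop("invalid distance: must be positive")
  1 / distance_cm
}

#' Simple standardized linear regression
#'
#' Fits `scale(y) ~ scale(x)`; the standardized slope b equals the Pearson
#' correlation, and the identities `R^2 = b^2`, `F = t^2` hold exactly.
#'
#' @param y Criterion.
#' @param x Predictor (non-constant, n >= 3 complete pairs).
#' @return An object of class `regression_result`: `b`, `t`, `F`, `df1`,
#'   `df2`, `r_squared`, `adj_r_squared`, `p`.
#' @export
simple_regression <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance")
  if (stats::var(y) == 0) stop("degenerate criterion: zero variance")
  fit <- stats::lm(scale(y) ~ scale(x))
  sm <- summary(fit)
  b <- unname(stats::coef(fit)[2L])
  tstat <- unname(sm$coefficients[2L, "t value"])
  structure(list(b = b, t = tstat, F = tstat^2, df1 = 1L, df2 = n - 2L,
                 r_squared = unname(sm$r.squared),
                 adj_r_squared = unname(sm$adj.r.squared),
                 p = unname(sm$coefficients[2L, "Pr(>|t|)"])),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("standardized regression: b = %.3f, t = %.3f, F(1, %d) = %.3f, p = %.4f, R2 = %.3f (adj %.3f)\n",
              x$b, x$t, x$df2, x$F, x$p, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Multivariate outlier screen (squared Mahalanobis distance)
#'
#' Flags rows whose squared Mahalanobis distance from the column means
#' exceeds the chi-square quantile at 1 - alpha with p degrees of freedom.
#' A labelled stand-in for by-eye multivariate outlier screening.
#'
#' @param x Numeric matrix or data.frame (rows = cases, >= p + 2 rows).
#' @param alpha Tail probability for the chi-square cut (default 0.001).
#' @return List with `flagged` (row indices), `d2` (distances), `cutoff`.
#' @export
mahalanobis_outliers <- function(x, alpha = 0.001) {
  x <- as.matrix(x)
  p <- ncol(x); n <- nrow(x)
  if (n < p + 2) stop("need at least p + 2 rows")
  S <- stats::cov(x)
  if (abs(det(S)) < 1e-12 * prod(diag(S) + 1e-300))
    stop("singular covariance")
  d2 <- stats::mahalanobis(x, colMeans(x), S)
  cutoff <- stats::qchisq(1 - alpha, df = p)
  list(flagged = which(d2 > cutoff), d2 = d2, cutoff = cutoff)
}
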