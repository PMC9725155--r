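# The inferential battery: Levene's test for homogeneity of variance,
# ANOVA F / Welch ANOVA / Welch's t for means, Spearman correlation,
# Bonferroni correction and post-hoc power, plus the eccentricity
# regression on per-target means and the per-participant divergence/error
# correlation analysis. All tests are two-tailed.

new_stat_result <- function(test, statistic, dof1, dof2 = NA_real_,
                            p_value, p_adjusted = NA_real_,
                            power = NA_real_) {
  structure(
    list(test = test, statistic = statistic, dof1 = dof1, dof2 = dof2,
         p_value = p_value, p_adjusted = p_adjusted, power = power),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  dof <- if (is.na(x$dof2)) sprintf("%.4g", x$dof1) else
    sprintf("%.4g, %.4g", x$dof1, x$dof2)
  cat(sprintf("%s: statistic = %.4f, dof = (%s), p = %.4g\n",
              x$test, x$statistic, dof, x$p_value))
  invisible(x)
}

check_samples <- function(samples, min_n = 2L) {
  if (!is.list(samples) || length(samples) < 2L) {
    al_stop("need a list of at least 2 samples")
  }
  sizes <- lengths(samples)
  if (any(sizes < min_n)) {
    al_stop(sprintf("every sample needs at least %d observations", min_n))
  }
  invisible(sizes)
}

stack_samples <- function(samples) {
  list(values = unlist(samples, use.names = FALSE),
       g = factor(rep(seq_along(samples), lengths(samples))))
}

#' Levene's test for homogeneity of variance
#'
#' Classical Levene test with mean centering: a one-way ANOVA on the
#' absolute deviations of each observation from its group mean. Median
#' centering (the Brown-Forsythe variant) is available via `center`.
#'
#' @param samples List of 2 or more numeric vectors (each of length >= 2).
#' @param center `"mean"` (classical Levene, the default) or `"median"`
#'   (Brown-Forsythe).
#' @return A `"stat_result"` with the W statistic, (k-1, N-k) degrees of
#'   freedom and the two-tailed p-value.
#' @export
levene_test <- function(samples, center = c("mean", "median")) {
  center <- match.arg(center)
  check_samples(samples)
  st <- stack_samples(samples)
  centerfun <- if (center == "mean") mean else stats::median
  tab <- car::leveneTest(st$values, st$g, center = centerfun)
  new_stat_result("levene",
                  statistic = tab[1, "F value"],
                  dof1 = tab[1, "Df"], dof2 = tab[2, "Df"],
                  p_value = tab[1, "Pr(>F)"])
}

#' One-way ANOVA F test (equal variances assumed)
#'
#' @param samples List of 2 or more numeric vectors.
#' @return A `"stat_result"` with F, (k-1, N-k) dof and p.
#' @export
anova_f <- function(samples) {
  check_samples(samples)
  st <- stack_samples(samples)
  fit <- stats::oneway.test(st$values ~ st$g, var.equal = TRUE)
  new_stat_result("anova_f", statistic = unname(fit$statistic),
                  dof1 = unname(fit$parameter[1]),
                  dof2 = unname(fit$parameter[2]),
                  p_value = fit$p.value)
}

#' One-way Welch ANOVA (unequal variances)
#'
#' Welch's heteroscedastic F with Welch-Satterthwaite denominator degrees
#' of freedom. For two groups the statistic equals the square of Welch's
#' t.
#'
#' @param samples List of 2 or more numeric vectors.
#' @return A `"stat_result"`.
#' @export
welch_anova <- function(samples) {
  check_samples(samples)
  st <- stack_samples(samples)
  fit <- stats::oneway.test(st$values ~ st$g, var.equal = FALSE)
  new_stat_result("welch_anova", statistic = unname(fit$statistic),
                  dof1 = unname(fit$parameter[1]),
                  dof2 = unname(fit$parameter[2]),
                  p_value = fit$p.value)
}

#' Welch's two-sample t test (unequal variances)
#'
#' @param sample_a,sample_b Numeric vectors of length >= 2.
#' @return A `"stat_result"` with t, Welch-Satterthwaite dof and the
#'   two-tailed p-value.
#' @export
welch_t <- function(sample_a, sample_b) {
  check_samples(list(sample_a, sample_b))
  fit <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  new_stat_result("welch_t", statistic = unname(fit$statistic),
                  dof1 = unname(fit$parameter),
                  p_value = fit$p.value)
}

#' Spearman rank correlation
#'
#' Spearman's rho on average-ranked data (ties get average ranks), with
#' the two-tailed large-sample p-value; identical to a Pearson
#' correlation computed on the ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `"stat_result"` with rho as the statistic and `n - 2`
#'   degrees of freedom.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) al_stop("x and y must have equal length")
  if (length(x) < 3L) al_stop("need at least 3 paired observations")
  fit <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  new_stat_result("spearman", statistic = unname(fit$estimate),
                  dof1 = length(x) - 2, p_value = fit$p.value)
}

#' Bonferroni correction
#'
#' Adjusts each p-value to `min(1, m * p)` for an explicitly declared
#' family of `m` comparisons. `m` may exceed the number of p-values
#' passed (the family size is a design choice, not a vector length).
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons in the family (`m >= length(p_values)`).
#' @return Adjusted p-values, same order as the input.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (m < length(p_values)) {
    al_stop("family size m must be at least the number of p-values")
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    al_stop("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Post-hoc power from the observed standardized effect
#'
#' Power at `alpha` for the achieved design, from the noncentral t (two
#' samples) or noncentral F (one-way, k groups) distribution. Two-sample
#' designs take Cohen's d; one-way designs take Cohen's f.
#'
#' @param result A `"stat_result"` from [welch_t()], [welch_anova()] or
#'   [anova_f()] (used to pick the reference distribution and its
#'   degrees of freedom).
#' @param sizes Integer vector of group sizes.
#' @param effect Observed standardized effect (d for two-sample t, f for
#'   one-way designs).
#' @param alpha Significance level (default 0.05).
#' @return Power in `[0, 1]`. With a zero effect this is exactly `alpha`.
#' @export
posthoc_power <- function(result, sizes, effect, alpha = 0.05) {
  if (!inherits(result, "stat_result")) al_stop("result must be a stat_result")
  if (result$test == "welch_t" ||
      (result$test %in% c("welch_anova", "anova_f") && length(sizes) == 2L)) {
    if (length(sizes) != 2L) {
      al_stop("two-sample power needs exactly 2 group sizes")
    }
    n1 <- sizes[1]; n2 <- sizes[2]
    ncp <- abs(effect) / sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
    tcrit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
  } else if (result$test %in% c("welch_anova", "anova_f")) {
    k <- length(sizes)
    if (k < 2L) al_stop("one-way power needs at least 2 group sizes")
    n_tot <- sum(sizes)
    ncp <- effect^2 * n_tot
    df1 <- k - 1
    df2 <- n_tot - k
    fcrit <- stats::qf(1 - alpha, df1, df2)
    1 - stats::pf(fcrit, df1, df2, ncp)
  } else {
    al_stop(paste0("power not implemented for test: ", result$test),
            "not_implemented")
  }
}

new_regression_fit <- function(slope, intercept, r_squared, n_points) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = n_points),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope = %.4g, intercept = %.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

# OLS of y on x with the package's zero-variance convention: when the
# response has no variance, slope is 0 and r^2 is defined as 0.
ols_fit <- function(x, y) {
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.xmin) {
    return(new_regression_fit(0, mean(y), 0, length(y)))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; r^2 = 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_regression_fit(unname(stats::coef(fit)[2]),
                     unname(stats::coef(fit)[1]),
                     r2,
                     length(y))
}

#' Eccentricity regression on per-target means
#'
#' Averages a per-trial measure at each target azimuth and fits an
#' ordinary least-squares line to those (at most 13) means against
#' azimuth. This is a fit ON THE MEANS, not on the raw trials: it
#' captures how the central tendency of the measure scales with target
#' eccentricity (e.g. the undershoot of signed errors toward the
#' midline).
#'
#' @param metrics Metrics data frame.
#' @param measure Column to average (e.g. `"signed_error"`,
#'   `"head_divergence"`).
#' @param condition,group Optional filters (`"R"`/`"V"`, `"G_R"`/`"G_V"`).
#' @param exclude_outliers Drop flagged trials first (default `TRUE`).
#' @return A `"regression_fit"` (slope, intercept, r-squared, number of
#'   azimuth means used). At least 3 azimuths with data are required.
#' @export
eccentricity_regression <- function(metrics, measure,
                                    condition = NULL, group = NULL,
                                    exclude_outliers = TRUE) {
  if (!measure %in% names(metrics)) {
    al_stop(paste0("unknown measure: ", measure))
  }
  if (!is.null(condition)) {
    metrics <- metrics[metrics$condition %in% condition, , drop = FALSE]
  }
  if (!is.null(group)) {
    metrics <- metrics[metrics$group %in% group, , drop = FALSE]
  }
  if (exclude_outliers && "is_outlier" %in% names(metrics)) {
    metrics <- metrics[!metrics$is_outlier, , drop = FALSE]
  }
  az <- sort(unique(metrics$target_az))
  if (length(az) < 3L) {
    al_stop("need data at 3 or more distinct target azimuths")
  }
  means <- vapply(az, function(a) {
    mean(metrics[[measure]][metrics$target_az == a])
  }, numeric(1))
  ols_fit(az, means)
}

#' Per-participant correlation of head divergence with signed error
#'
#' For each participant (after the optional condition/group filter),
#' Spearman's rho between head divergence at the response and the signed
#' pointing error, with its two-tailed p-value and a significance flag at
#' `alpha`. Per-participant mean signed and unsigned errors are returned
#' alongside, both raw and normalized to [-1, 1] across participants (for
#' compact comparative display).
#'
#' @param metrics Metrics data frame.
#' @param condition,group Optional filters.
#' @param alpha Significance level for the flag (default 0.05).
#' @param exclude_outliers Drop flagged trials first (default `TRUE`).
#' @return A data frame with one row per participant: `participant_id`,
#'   `n`, `rho`, `p_value`, `significant`, `mean_signed`,
#'   `mean_unsigned`, `mean_signed_norm`, `mean_unsigned_norm`, sorted by
#'   ascending rho.
#' @export
per_participant_spearman <- function(metrics, condition = NULL, group = NULL,
                                     alpha = 0.05, exclude_outliers = TRUE) {
  if (!is.null(condition)) {
    metrics <- metrics[metrics$condition %in% condition, , drop = FALSE]
  }
  if (!is.null(group)) {
    metrics <- metrics[metrics$group %in% group, , drop = FALSE]
  }
  if (exclude_outliers && "is_outlier" %in% names(metrics)) {
    metrics <- metrics[!metrics$is_outlier, , drop = FALSE]
  }
  ids <- unique(metrics$participant_id)
  if (length(ids) == 0L) al_stop("no participants after filtering")
  rows <- lapply(ids, function(pid) {
    sub <- metrics[metrics$participant_id == pid, , drop = FALSE]
    if (nrow(sub) < 3L) {
      al_stop(sprintf("participant %s has fewer than 3 trials", pid))
    }
    res <- spearman_test(sub$head_divergence, sub$signed_error)
    data.frame(participant_id = pid, n = nrow(sub),
               rho = res$statistic, p_value = res$p_value,
               significant = res$p_value < alpha,
               mean_signed = mean(sub$signed_error),
               mean_unsigned = mean(sub$unsigned_error),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  norm_to_unit <- function(v) {
    mx <- max(abs(v))
    if (mx == 0) v else v / mx
  }
  out$mean_signed_norm <- norm_to_unit(out$mean_signed)
  out$mean_unsigned_norm <- norm_to_unit(out$mean_unsigned)
  out <- out[order(out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}
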