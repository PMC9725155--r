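# Pipeline orchestration: read -> kinematics -> per-trial metrics ->
# outlier filter -> group summaries -> inferential battery ->
# eccentricity fits -> per-participant correlations -> envelope analysis
# -> quartile split, with all result surfaces written as CSV/JSON under a
# manifest.

#' Outlier bookkeeping summary
#'
#' Counts flagged trials and reports the percentage both raw (full
#' precision) and rounded to two decimals. Both are emitted because a
#' truncated display percentage cannot be recovered from the rounded one.
#'
#' @param metrics Metrics data frame with an `is_outlier` column, or a
#'   single flagged count (then `n_total` must be given).
#' @param n_total Total number of trials when `metrics` is a count.
#' @return A list with `n_flagged`, `n_total`, `pct_raw`
#'   (`100 * n_flagged / n_total`) and `pct` (2-decimal rounding).
#' @export
outlier_summary <- function(metrics, n_total = NULL) {
  if (is.data.frame(metrics)) {
    if (!"is_outlier" %in% names(metrics)) {
      al_stop("metrics have not been flagged: run flag_outliers() first")
    }
    n_flagged <- sum(metrics$is_outlier)
    n_total <- nrow(metrics)
  } else {
    n_flagged <- metrics
    if (is.null(n_total)) al_stop("n_total is required with a flagged count")
  }
  if (n_total == 0L) al_stop("n_total must be positive")
  pct_raw <- 100 * n_flagged / n_total
  list(n_flagged = as.integer(n_flagged), n_total = as.integer(n_total),
       pct_raw = pct_raw, pct = round(pct_raw, 2))
}

# One family of the battery: Levene on the two samples decides between the
# classical ANOVA F (homoscedastic) and Welch (heteroscedastic), per the
# decision rule of the modeled study; power is computed post hoc from the
# observed standardized effect.
compare_two <- function(a, b, label, alpha = 0.05) {
  lev <- levene_test(list(a, b))
  homo <- lev$p_value >= alpha
  mean_test <- if (homo) anova_f(list(a, b)) else welch_t(a, b)
  sd_pool <- sqrt(((length(a) - 1) * stats::var(a) +
                   (length(b) - 1) * stats::var(b)) /
                  (length(a) + length(b) - 2))
  d <- if (sd_pool > 0) abs(mean(a) - mean(b)) / sd_pool else 0
  mean_test$power <- posthoc_power(mean_test, c(length(a), length(b)), d,
                                   alpha = alpha)
  rbind(
    data.frame(analysis = label, test = lev$test, statistic = lev$statistic,
               dof1 = lev$dof1, dof2 = lev$dof2, p = lev$p_value,
               p_adj = NA_real_, power = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(analysis = label, test = mean_test$test,
               statistic = mean_test$statistic,
               dof1 = mean_test$dof1, dof2 = mean_test$dof2,
               p = mean_test$p_value, p_adj = NA_real_,
               power = mean_test$power, stringsAsFactors = FALSE)
  )
}

#' Run the full inferential battery on a metrics table
#'
#' For each measure, four pairwise comparisons form one Bonferroni family
#' (m = 4): between groups within each condition, and between conditions
#' within each group. Each comparison runs Levene's test, then the ANOVA
#' F (variance homogeneity holds at `alpha`) or Welch's t (it does not)
#' on the means, with post-hoc power from the observed effect.
#'
#' @param metrics Flagged metrics data frame.
#' @param measures Columns to analyse.
#' @param alpha Significance level.
#' @param exclude_outliers Drop flagged trials first.
#' @return A tidy data frame: `analysis`, `test`, `statistic`, `dof1`,
#'   `dof2`, `p`, `p_adj` (Bonferroni within the measure's family, mean
#'   tests only), `power`.
#' @export
run_stat_battery <- function(metrics,
                             measures = c("signed_error", "unsigned_error",
                                          "latency", "head_divergence",
                                          "head_distance"),
                             alpha = 0.05,
                             exclude_outliers = TRUE) {
  if (exclude_outliers && "is_outlier" %in% names(metrics)) {
    metrics <- metrics[!metrics$is_outlier, , drop = FALSE]
  }
  cell <- function(g, cond, measure) {
    metrics[[measure]][metrics$group == g & metrics$condition == cond]
  }
  out <- list()
  for (measure in measures) {
    fam <- rbind(
      compare_two(cell("G_R", "R", measure), cell("G_V", "R", measure),
                  paste0(measure, ": G_R vs G_V in R"), alpha),
      compare_two(cell("G_R", "V", measure), cell("G_V", "V", measure),
                  paste0(measure, ": G_R vs G_V in V"), alpha),
      compare_two(cell("G_R", "R", measure), cell("G_R", "V", measure),
                  paste0(measure, ": R vs V in G_R"), alpha),
      compare_two(cell("G_V", "R", measure), cell("G_V", "V", measure),
                  paste0(measure, ": R vs V in G_V"), alpha)
    )
    is_mean_test <- fam$test != "levene"
    fam$p_adj[is_mean_test] <- bonferroni(fam$p[is_mean_test],
                                          m = sum(is_mean_test))
    fam$family_m <- ifelse(is_mean_test, sum(is_mean_test), NA_integer_)
    out[[measure]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the complete analysis pipeline
#'
#' Reads a trial log and its trajectories, derives per-trial metrics,
#' applies the outlier filter, and produces every result surface of the
#' analysis: group-by-condition summaries of all five measures, the
#' inferential battery, eccentricity regressions, per-participant
#' divergence/error correlations, the envelope regression table, the
#' quadrant-partition curve and the quartile-split divergence comparison
#' for the virtual-first group in the virtual condition. All tables are
#' written under `outdir` together with a JSON manifest carrying file
#' checksums and provenance (config, package version).
#'
#' @param trials_path Path to the trial-log CSV.
#' @param trajectories_path Path to the long-format trajectory CSV.
#' @param config A `"study_config"`, a path to a YAML config, or `NULL`
#'   for defaults.
#' @param outdir Output directory (created if needed).
#' @return A list of class `"audioloc_report"` holding all computed
#'   objects plus `paths` and `manifest`.
#' @export
run_pipeline <- function(trials_path, trajectories_path, config = NULL,
                         outdir) {
  cfg <- if (is.null(config)) {
    study_config()
  } else if (is.character(config)) {
    read_study_config(config)
  } else {
    validate_study_config(config)
    config
  }
  trials <- read_trial_log(trials_path, azimuth_set = cfg$azimuth_set)
  trajectories <- read_trajectories(trajectories_path)
  metrics <- compute_trial_metrics(trials, trajectories)
  metrics <- flag_outliers(metrics, k = cfg$outlier_k,
                           strata = cfg$outlier_strata)
  outliers <- outlier_summary(metrics)
  kept <- metrics[!metrics$is_outlier, , drop = FALSE]

  measures <- c("signed_error", "unsigned_error", "latency",
                "head_divergence", "head_distance")
  summaries <- do.call(rbind, lapply(measures, function(m) {
    summarize_metrics(metrics, m, by = c("group", "condition"))
  }))

  stats_table <- run_stat_battery(metrics, measures = measures,
                                  alpha = cfg$alpha)

  # eccentricity fits: signed error for the virtual-first group in V, and
  # head divergence in each condition for the same group
  ecc <- list(
    signed_error_V = eccentricity_regression(metrics, "signed_error",
                                             condition = "V", group = "G_V"),
    divergence_R = eccentricity_regression(metrics, "head_divergence",
                                           condition = "R", group = "G_V"),
    divergence_V = eccentricity_regression(metrics, "head_divergence",
                                           condition = "V", group = "G_V")
  )
  ecc_table <- data.frame(
    analysis = names(ecc),
    slope = vapply(ecc, function(f) f$slope, numeric(1)),
    intercept = vapply(ecc, function(f) f$intercept, numeric(1)),
    r_squared = vapply(ecc, function(f) f$r_squared, numeric(1)),
    n_points = vapply(ecc, function(f) f$n_points, numeric(1)),
    stringsAsFactors = FALSE
  )

  correlations <- per_participant_spearman(metrics, condition = "V",
                                           group = "G_V", alpha = cfg$alpha)

  # envelope analysis on the virtual-first group in the virtual condition
  env_data <- kept[kept$group == "G_V" & kept$condition == "V", , drop = FALSE]
  eps <- env_data$unsigned_error
  h <- env_data$head_distance
  max_error <- max(eps)
  env_rows <- list()
  envelopes <- list()
  for (lvl in names(cfg$envelope_levels)) {
    k_sd <- cfg$envelope_levels[[lvl]]
    bb <- bin_upper_bounds(eps, h, k_sd = k_sd, bin_width = cfg$bin_width)
    lin <- fit_linear_envelope(bb$bin_centers, bb$upper_bounds)
    logf <- fit_log_envelope(bb$bin_centers, bb$upper_bounds, max_error)
    envelopes[[lvl]] <- list(k_sd = k_sd, bounds = bb, linear = lin,
                             log = logf, max_error = max_error)
    env_rows[[lvl]] <- data.frame(
      regression_type = c("linear", "logarithmic"),
      level = lvl,
      slope_or_A = c(lin$slope, logf$A),
      intercept_or_B = c(lin$intercept, logf$B),
      r_squared = c(lin$r_squared, logf$r_squared),
      n_bins = c(lin$n_points, logf$n_points),
      stringsAsFactors = FALSE
    )
  }
  envelope_table <- do.call(rbind, env_rows)
  rownames(envelope_table) <- NULL

  qcurve <- quadrant_curve(eps, h, fraction = cfg$quadrant_fraction)
  qsplit <- quartile_split_divergence(env_data)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    metrics = write_metrics_table(metrics, file.path(outdir, "metrics.csv")),
    group_summaries = write_table(summaries,
                                  file.path(outdir, "group_summaries.csv")),
    stats = write_table(stats_table, file.path(outdir, "stats.csv")),
    eccentricity = write_table(ecc_table,
                               file.path(outdir, "eccentricity.csv")),
    correlations = write_table(correlations,
                               file.path(outdir,
                                         "participant_correlations.csv")),
    envelope = write_table(envelope_table,
                           file.path(outdir, "envelope_table.csv")),
    quadrant_curve = write_table(qcurve$points,
                                 file.path(outdir, "quadrant_curve.csv"))
  )
  results_json <- file.path(outdir, "results.json")
  jsonlite::write_json(
    list(outliers = outliers,
         quartile_split = qsplit,
         quadrant = list(fraction = qcurve$fraction, k = qcurve$k,
                         n_total = qcurve$n_total)),
    results_json, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, results = results_json)

  manifest <- list(
    files = lapply(stats::setNames(nm = names(paths)), function(nm) {
      list(path = basename(paths[[nm]]),
           md5 = unname(tools::md5sum(paths[[nm]])))
    }),
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(write_config_tmp(cfg))),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("audioloc"))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  structure(
    list(metrics = metrics, outliers = outliers,
         group_summaries = summaries, stats_table = stats_table,
         eccentricity = ecc, eccentricity_table = ecc_table,
         correlations = correlations, envelopes = envelopes,
         envelope_table = envelope_table, quadrant_curve = qcurve,
         quartile_split = qsplit, config = cfg,
         paths = c(paths, manifest = manifest_path), manifest = manifest),
    class = "audioloc_report"
  )
}

# Serialize the config to a temp YAML file so its checksum can go in the
# manifest (hash of content, independent of in-memory representation).
write_config_tmp <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.matrix(x)) as.list(as.data.frame(x)) else x
  }), tmp)
  tmp
}

#' @export
print.audioloc_report <- function(x, ...) {
  cat("audioloc analysis report\n")
  cat(sprintf("  trials: %d (%d outliers, %.4g%%)\n",
              x$outliers$n_total, x$outliers$n_flagged, x$outliers$pct_raw))
  cat(sprintf("  envelope levels: %s\n",
              paste(names(x$envelopes), collapse = ", ")))
  cat(sprintf("  quadrant curve: %d corners (k = %d)\n",
              nrow(x$quadrant_curve$points), x$quadrant_curve$k))
  cat(sprintf("  outputs: %s\n", dirname(x$paths[["metrics"]])))
  invisible(x)
}
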