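# Per-trial response measures and the outlier filter.

#' Signed localization error
#'
#' Directed azimuth error of a pointing response, defined as
#' `pointed_az - target_az` wrapped into (-180, 180]. Under the package's
#' rightward-positive azimuth convention a positive signed error is a
#' response to the right of the target, so a positive group mean reads
#' directly as a rightward response bias.
#'
#' @param target_az,pointed_az Azimuths in degrees in (-180, 180].
#'   Vectorized.
#' @return Signed error in degrees in (-180, 180].
#' @seealso [unsigned_error()]
#' @export
signed_error <- function(target_az, pointed_az) {
  wrap_angle(pointed_az - target_az)
}

#' Unsigned localization error
#'
#' Absolute azimuth error, the study's accuracy measure (symbol
#' \eqn{\epsilon}).
#'
#' @param signed Signed error in degrees.
#' @return `abs(signed)`.
#' @export
unsigned_error <- function(signed) {
  abs(signed)
}

#' Derive per-trial metrics from a trial log and its trajectories
#'
#' For every trial: signed and unsigned pointing error, response latency
#' (`t_hit - t_onset`), head divergence at the response (target azimuth
#' minus head yaw at the sample nearest `t_hit`), and cumulative head
#' path length over `[t_onset, t_hit]`. The outlier flag is initialised
#' to `FALSE`; run [flag_outliers()] afterwards.
#'
#' @param trials Trial log data frame from [read_trial_log()].
#' @param trajectories Named trajectory list from [read_trajectories()].
#' @return A data frame with one row per trial: `trial_id`,
#'   `participant_id`, `group`, `condition`, `target_az`, `pointed_az`,
#'   `signed_error`, `unsigned_error`, `latency`, `head_divergence`,
#'   `head_distance`, `is_outlier`.
#' @export
compute_trial_metrics <- function(trials, trajectories) {
  missing_traj <- setdiff(trials$trajectory_ref, names(trajectories))
  if (length(missing_traj)) {
    al_stop(paste0("no trajectory found for trial(s): ",
                   paste(utils::head(missing_traj, 5), collapse = ", ")),
            "consistency")
  }
  n <- nrow(trials)
  div <- numeric(n)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    traj <- trajectories[[trials$trajectory_ref[i]]]
    yaw <- yaw_at_hit(traj, trials$t_hit[i])
    div[i] <- head_divergence(trials$target_az[i], yaw)
    dist[i] <- head_distance(traj, trials$t_onset[i], trials$t_hit[i])
  }
  se <- signed_error(trials$target_az, trials$pointed_az)
  data.frame(
    trial_id = trials$trial_id,
    participant_id = trials$participant_id,
    group = trials$group,
    condition = trials$condition,
    target_az = trials$target_az,
    pointed_az = trials$pointed_az,
    signed_error = se,
    unsigned_error = unsigned_error(se),
    latency = trials$t_hit - trials$t_onset,
    head_divergence = div,
    head_distance = dist,
    is_outlier = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Flag outlier trials by unsigned error
#'
#' Within each stratum, trials whose unsigned error exceeds
#' `mean + k * SD` (sample SD, strictly greater) are flagged. This is a
#' single pass: flags are set but no record is deleted — exclusion is the
#' caller's choice. Strata with fewer than 2 trials cannot yield an SD
#' and are left unflagged with a warning.
#'
#' @param metrics Metrics data frame from [compute_trial_metrics()].
#' @param k SD multiplier of the threshold (default 2).
#' @param strata Pooling level: `"per_condition"` (per target location
#'   within each condition, pooled across participants — the default),
#'   `"fully_pooled"` (per target location only), or `"per_participant"`
#'   (per target location within participant and condition).
#' @return `metrics` with `is_outlier` set.
#' @export
flag_outliers <- function(metrics,
                          k = 2,
                          strata = c("per_condition", "fully_pooled",
                                     "per_participant")) {
  strata <- match.arg(strata)
  if (!is.numeric(k) || k <= 0) al_stop("k must be > 0")
  key <- switch(strata,
    per_condition = interaction(metrics$target_az, metrics$condition,
                                drop = TRUE),
    fully_pooled = factor(metrics$target_az),
    per_participant = interaction(metrics$target_az, metrics$condition,
                                  metrics$participant_id, drop = TRUE)
  )
  flags <- logical(nrow(metrics))
  thin <- character(0)
  for (s in levels(key)) {
    idx <- which(key == s)
    if (length(idx) < 2L) {
      thin <- c(thin, s)
      next
    }
    e <- metrics$unsigned_error[idx]
    flags[idx] <- e > mean(e) + k * stats::sd(e)
  }
  if (length(thin)) {
    al_warn(paste0("stratum/strata with fewer than 2 trials left unflagged: ",
                   paste(thin, collapse = ", ")))
  }
  metrics$is_outlier <- flags
  metrics
}

#' Summarize a per-trial measure by grouping cells
#'
#' Mean and sample SD of a chosen measure per cell (by default group x
#' condition), optionally excluding flagged outliers. Cells holding a
#' single trial have no sample SD; they are reported with `sd = 0` and a
#' zero-variance warning.
#'
#' @param metrics Metrics data frame.
#' @param measure Name of the numeric column to summarize.
#' @param by Character vector of grouping columns.
#' @param exclude_outliers Drop rows with `is_outlier = TRUE` first?
#' @return A data frame with the grouping columns plus `n`, `mean`, `sd`.
#' @export
summarize_metrics <- function(metrics, measure,
                              by = c("group", "condition"),
                              exclude_outliers = TRUE) {
  if (!measure %in% names(metrics) || !is.numeric(metrics[[measure]])) {
    al_stop(paste0("unknown or non-numeric measure: ", measure))
  }
  if (!all(by %in% names(metrics))) {
    al_stop(paste0("unknown grouping column(s): ",
                   paste(setdiff(by, names(metrics)), collapse = ", ")))
  }
  if (exclude_outliers && "is_outlier" %in% names(metrics)) {
    metrics <- metrics[!metrics$is_outlier, , drop = FALSE]
  }
  if (nrow(metrics) == 0L) al_stop("no trials left to summarize")
  key <- interaction(metrics[by], drop = TRUE, sep = "\r")
  cells <- lapply(levels(key), function(s) {
    idx <- which(key == s)
    v <- metrics[[measure]][idx]
    sdv <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    c(n = length(v), mean = mean(v), sd = sdv)
  })
  labels <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(labels, stringsAsFactors = FALSE)
  names(out) <- by
  stats_mat <- do.call(rbind, cells)
  out$n <- as.integer(stats_mat[, "n"])
  out$mean <- stats_mat[, "mean"]
  out$sd <- stats_mat[, "sd"]
  if (anyNA(out$sd)) {
    al_warn("cell(s) with a single trial: sd reported as 0 (zero variance)")
    out$sd[is.na(out$sd)] <- 0
  }
  out$measure <- measure
  out
}

#' Bin values into fixed-width degree bins
#'
#' Bins are centered on integer multiples of `width` and half-open:
#' value `v` falls in the bin with center `c` when
#' `c - width/2 <= v < c + width/2`. With the default 1-degree width this
#' matches a pointer whose angular resolution is one degree.
#'
#' @param values Numeric vector (degrees).
#' @param width Bin width in degrees (> 0).
#' @return A named list mapping bin center (as character) to the values
#'   assigned to that bin, in ascending center order.
#' @export
bin_by_degree <- function(values, width = 1) {
  if (!is.numeric(width) || width <= 0) al_stop("width must be > 0")
  if (length(values) == 0L) return(structure(list(), names = character()))
  centers <- width * floor(values / width + 0.5)
  split(values, factor(centers, levels = sort(unique(centers))))
}
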