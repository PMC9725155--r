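# Readers and writers for trial logs, head-tracking trajectories, derived
# metrics tables, and the study configuration. All files are comma-
# delimited UTF-8 text with a header row; trajectories are long format
# keyed by trial_id. Timestamps are seconds from session start.

TRIAL_LOG_COLUMNS <- c("trial_id", "participant_id", "group", "condition",
                       "target_az", "pointed_az", "t_onset", "t_hit",
                       "trajectory_ref")
TRAJECTORY_COLUMNS <- c("trial_id", "t", "x", "y", "z",
                        "qw", "qx", "qy", "qz")

#' Default analysis configuration
#'
#' Bundles the tunable constants of the analysis pipeline. All defaults
#' mirror the study protocol this package models: 13 azimuths from -90 to
#' +90 degrees in 15-degree steps, 5 repetitions per target, 1-degree
#' error bins, an outlier cut of 2 SD above the per-target mean unsigned
#' error, envelope levels at 1.96 SD ("95") and 3 SD ("99.7"), a 5%
#' quadrant-partition fraction, and alpha = 0.05.
#'
#' @param azimuth_set Valid target azimuths in degrees.
#' @param reps_per_target Stimulus repetitions per azimuth and condition.
#' @param bin_width Unsigned-error bin width in degrees (> 0).
#' @param outlier_k SD multiplier of the outlier threshold (> 0).
#' @param outlier_strata Pooling level of the outlier filter: per target
#'   location within condition (default), fully pooled across conditions,
#'   or per participant.
#' @param envelope_levels Named numeric vector of SD multipliers for the
#'   upper confidence envelopes.
#' @param quadrant_fraction Fraction of points each upper-right quadrant
#'   of the partition curve must contain (in (0, 1)).
#' @param alpha Significance level for the inferential battery.
#' @param seed Integer seed recorded in reports for provenance.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(azimuth_set = seq(-90, 90, by = 15),
                         reps_per_target = 5L,
                         bin_width = 1,
                         outlier_k = 2,
                         outlier_strata = c("per_condition", "fully_pooled",
                                            "per_participant"),
                         envelope_levels = c("95" = 1.96, "99.7" = 3),
                         quadrant_fraction = 0.05,
                         alpha = 0.05,
                         seed = 1L) {
  outlier_strata <- match.arg(outlier_strata)
  cfg <- list(azimuth_set = azimuth_set,
              reps_per_target = as.integer(reps_per_target),
              bin_width = bin_width,
              outlier_k = outlier_k,
              outlier_strata = outlier_strata,
              envelope_levels = envelope_levels,
              quadrant_fraction = quadrant_fraction,
              alpha = alpha,
              seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (!is.numeric(cfg$bin_width) || cfg$bin_width <= 0) {
    al_stop("bin_width must be > 0")
  }
  if (!is.numeric(cfg$outlier_k) || cfg$outlier_k <= 0) {
    al_stop("outlier_k must be > 0")
  }
  if (cfg$quadrant_fraction <= 0 || cfg$quadrant_fraction >= 1) {
    al_stop("quadrant_fraction must lie strictly between 0 and 1")
  }
  if (is.null(names(cfg$envelope_levels)) || any(cfg$envelope_levels <= 0)) {
    al_stop("envelope_levels must be a named vector of positive SD multipliers")
  }
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [study_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"study_config"` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) al_stop(paste0("config file not found: ", path), "io")
  raw <- yaml::read_yaml(path)
  defaults <- study_config()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    al_stop(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
            "format")
  }
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "envelope_levels") v <- unlist(v)
    defaults[[k]] <- v
  }
  do.call(study_config, unclass(defaults))
}

#' Read a trial log
#'
#' Reads a comma-delimited trial log with one row per trial and validates
#' it against the study grid: azimuth membership, group/condition labels,
#' integer pointer resolution, and response-after-onset ordering. Row
#' order is preserved.
#'
#' @param path Path to the CSV file. Required columns:
#'   `trial_id, participant_id, group, condition, target_az, pointed_az,
#'   t_onset, t_hit, trajectory_ref`.
#' @param azimuth_set Valid target azimuths (defaults to the 13-point
#'   grid from -90 to 90 in 15-degree steps).
#' @return A data frame with one validated row per trial.
#' @export
read_trial_log <- function(path, azimuth_set = seq(-90, 90, by = 15)) {
  if (!file.exists(path)) al_stop(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing_cols)) {
    al_stop(paste0("trial log is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  df <- df[TRIAL_LOG_COLUMNS]
  if (nrow(df) == 0L) return(df)

  df$trial_id <- as.character(df$trial_id)
  df$participant_id <- as.character(df$participant_id)
  df$trajectory_ref <- as.character(df$trajectory_ref)

  bad <- which(!df$group %in% c("G_R", "G_V"))
  if (length(bad)) {
    al_stop(sprintf("row %d: group '%s' is not one of G_R, G_V",
                    bad[1], df$group[bad[1]]))
  }
  bad <- which(!df$condition %in% c("R", "V"))
  if (length(bad)) {
    al_stop(sprintf("row %d: condition '%s' is not one of R, V",
                    bad[1], df$condition[bad[1]]))
  }
  bad <- which(!df$target_az %in% azimuth_set)
  if (length(bad)) {
    al_stop(sprintf("row %d: target_az = %s is not in the azimuth set",
                    bad[1], format(df$target_az[bad[1]])))
  }
  bad <- which(df$pointed_az != round(df$pointed_az))
  if (length(bad)) {
    al_stop(sprintf(
      "row %d: pointed_az = %s is not an integer number of degrees",
      bad[1], format(df$pointed_az[bad[1]])))
  }
  bad <- which(df$t_hit <= df$t_onset)
  if (length(bad)) {
    al_stop(sprintf("row %d: t_hit (%.3f) is not after t_onset (%.3f)",
                    bad[1], df$t_hit[bad[1]], df$t_onset[bad[1]]))
  }
  df
}

#' Read head trajectories
#'
#' Reads a long-format trajectory file (one row per tracker sample) and
#' groups samples by `trial_id` in order of first appearance. Timestamps
#' must be strictly increasing within each trial. Quaternions whose norm
#' deviates from 1 by at most `1e-3` are renormalized; larger deviations
#' are rejected as corrupt.
#'
#' @param path Path to a CSV with columns
#'   `trial_id, t, x, y, z, qw, qx, qy, qz`.
#' @param nominal_rate Nominal sampling rate in Hz, attached to each
#'   trajectory as an attribute (default 10).
#' @return A named list mapping `trial_id` to a trajectory data frame.
#' @export
read_trajectories <- function(path, nominal_rate = 10) {
  if (!file.exists(path)) al_stop(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(df))
  if (length(missing_cols)) {
    al_stop(paste0("trajectory file is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  df$trial_id <- as.character(df$trial_id)
  parts <- split(df[setdiff(TRAJECTORY_COLUMNS, "trial_id")],
                 factor(df$trial_id, levels = unique(df$trial_id)))
  lapply(parts, function(tr) {
    rownames(tr) <- NULL
    if (any(diff(tr$t) <= 0)) {
      al_stop("timestamps are not strictly increasing within a trial")
    }
    nrm <- sqrt(tr$qw^2 + tr$qx^2 + tr$qy^2 + tr$qz^2)
    if (any(abs(nrm - 1) > 1e-3)) {
      worst <- which.max(abs(nrm - 1))
      al_stop(sprintf(
        "quaternion norm %.6f deviates from 1 by more than 1e-3", nrm[worst]))
    }
    tr$qw <- tr$qw / nrm; tr$qx <- tr$qx / nrm
    tr$qy <- tr$qy / nrm; tr$qz <- tr$qz / nrm
    attr(tr, "nominal_rate") <- nominal_rate
    tr
  })
}

#' Write / read a per-trial metrics table
#'
#' Writes the derived metrics table as CSV at full double precision; the
#' outlier flag is stored as a 0/1 column. `read_metrics_table()` is the
#' matching reader, round-tripping numeric values to better than 1e-9.
#'
#' @param metrics A metrics data frame from [compute_trial_metrics()].
#' @param path Output path.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` returns the metrics data frame.
#' @export
write_metrics_table <- function(metrics, path) {
  out <- metrics
  if ("is_outlier" %in% names(out)) {
    out$is_outlier <- as.integer(out$is_outlier)
  }
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    formatted <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE)
    }, character(1))
    formatted
  })
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) al_stop(paste0("cannot write metrics table to ", path), "io")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) al_stop(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("is_outlier" %in% names(df)) df$is_outlier <- df$is_outlier != 0L
  df
}
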