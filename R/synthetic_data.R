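# Seeded generator of synthetic localization sessions: trial logs plus
# 10 Hz head trajectories with the statistical structure of a two-group,
# two-condition VR localization study. Every pipeline stage can be tested
# against the generating truth it emits.
#
# Behavioral model, per trial:
#   * a strategy is drawn: "dynamic" (active head search) with probability
#     p_dynamic, else "static";
#   * the pointing response undershoots the target toward the midline
#     (multiplicative shrinkage `undershoot_slope`), carries a
#     group-by-condition rightward bias, and adds Gaussian noise whose SD
#     is small for dynamic trials and larger for static ones — this
#     mixture produces the triangular head-distance-versus-error region
#     (movement is sufficient, not necessary, for accuracy) without
#     asserting any causal law;
#   * head orientation relaxes from straight ahead toward the target along
#     a damped exponential, ending at a drawn divergence from the target
#     (tight for dynamic trials, broad for static ones);
#   * only dynamic trials translate: the head sweeps an arc of radius
#     `pivot_radius` following yaw, plus a decaying search oscillation.
#     Static trials keep the head in place up to slow postural sway of
#     amplitude `jitter_sd` (white per-sample tracker noise is NOT used:
#     at 10 Hz it would add a spurious ~0.1 m of path per trial);
#   * latency is lognormal with a group-by-condition mean anchor.

#' Configuration of the synthetic study generator
#'
#' Defaults reproduce the modeled study protocol: 37 participants split
#' 17/20 into the two condition-order groups, 13 azimuths from -90 to 90
#' degrees in 15-degree steps, 5 repetitions per azimuth and condition
#' (65 trials per participant and condition, 4810 in total), a rightward
#' response bias of 0.6-2.5 degrees by group and condition, a 3%
#' eccentricity undershoot, latency means between about 3 and 4.3 s, and
#' head-divergence spread around 21 degrees for static trials versus 8
#' for dynamic ones.
#'
#' @param n_participants Number of participants.
#' @param n_group_R Number assigned to the group that starts with the
#'   real-listening condition (default 17 of 37; otherwise half, rounded
#'   down).
#' @param azimuths Target azimuths in degrees (frontal hemifield).
#' @param reps Repetitions per azimuth, condition and participant.
#' @param rightward_bias 2x2 matrix (rows `G_R`, `G_V`; columns `R`, `V`)
#'   of mean signed-error offsets in degrees, or a single number used for
#'   all cells.
#' @param undershoot_slope Unitless midline shrinkage of responses: the
#'   mean signed error changes by `-undershoot_slope` degrees per degree
#'   of target azimuth.
#' @param base_error_sd Named vector `c(R=, V=)` of response noise SD in
#'   degrees for static trials.
#' @param p_dynamic Probability of an active-search trial; scalar or
#'   named per condition `c(R=, V=)`.
#' @param dynamic_error_sd Response noise SD in degrees for dynamic trials.
#' @param divergence_mean_static,divergence_sd_static Mean/SD in degrees
#'   of the drawn head divergence on static trials.
#' @param divergence_mean_dynamic,divergence_sd_dynamic Same for dynamic
#'   trials.
#' @param pivot_radius Lever arm in meters converting yaw sweep into head
#'   translation on dynamic trials.
#' @param jitter_sd Amplitude scale in meters of the slow postural sway.
#' @param latency_mean 2x2 matrix (rows `G_R`, `G_V`; columns `R`, `V`)
#'   of mean latencies in seconds, or a single number.
#' @param latency_sdlog Log-scale SD of the lognormal latency draw.
#' @param n_coupled Number of second-group participants whose signed
#'   error is coupled to their head divergence (0 = off).
#' @param coupling_gain Degrees of signed error per degree of divergence
#'   for coupled participants.
#' @param sample_rate Tracker sampling rate in Hz.
#' @param seed Integer seed; all randomness flows through one stream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 37L,
                       n_group_R = NULL,
                       azimuths = seq(-90, 90, by = 15),
                       reps = 5L,
                       rightward_bias = matrix(
                         c(1.93, 2.47,
                           1.74, 0.60),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("G_R", "G_V"), c("R", "V"))),
                       undershoot_slope = 0.03,
                       base_error_sd = c(R = 2.8, V = 4.9),
                       p_dynamic = 0.3,
                       dynamic_error_sd = 1.5,
                       divergence_mean_static = 0.5,
                       divergence_sd_static = 21,
                       divergence_mean_dynamic = 0,
                       divergence_sd_dynamic = 8,
                       pivot_radius = 0.09,
                       jitter_sd = 0.002,
                       latency_mean = matrix(
                         c(2.99, 3.69,
                           3.50, 4.27),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("G_R", "G_V"), c("R", "V"))),
                       latency_sdlog = 0.45,
                       n_coupled = 0L,
                       coupling_gain = 0.25,
                       sample_rate = 10,
                       seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (is.null(n_group_R)) {
    n_group_R <- if (n_participants == 37L) 17L else n_participants %/% 2L
  }
  as_cell_matrix <- function(x, what) {
    if (is.matrix(x)) {
      if (!identical(dim(x), c(2L, 2L))) {
        al_stop(paste0(what, " matrix must be 2x2 (groups x conditions)"))
      }
      if (is.null(dimnames(x))) {
        dimnames(x) <- list(c("G_R", "G_V"), c("R", "V"))
      }
      x
    } else if (length(x) == 1L) {
      matrix(x, 2, 2, dimnames = list(c("G_R", "G_V"), c("R", "V")))
    } else {
      al_stop(paste0(what, " must be a scalar or a 2x2 matrix"))
    }
  }
  cfg <- list(
    n_participants = n_participants,
    n_group_R = as.integer(n_group_R),
    azimuths = azimuths,
    reps = as.integer(reps),
    rightward_bias = as_cell_matrix(rightward_bias, "rightward_bias"),
    undershoot_slope = undershoot_slope,
    base_error_sd = base_error_sd,
    p_dynamic = p_dynamic,
    dynamic_error_sd = dynamic_error_sd,
    divergence_mean_static = divergence_mean_static,
    divergence_sd_static = divergence_sd_static,
    divergence_mean_dynamic = divergence_mean_dynamic,
    divergence_sd_dynamic = divergence_sd_dynamic,
    pivot_radius = pivot_radius,
    jitter_sd = jitter_sd,
    latency_mean = as_cell_matrix(latency_mean, "latency_mean"),
    latency_sdlog = latency_sdlog,
    n_coupled = as.integer(n_coupled),
    coupling_gain = coupling_gain,
    sample_rate = sample_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 1L) al_stop("need at least 1 participant")
  if (cfg$n_group_R < 0L || cfg$n_group_R > cfg$n_participants) {
    al_stop("n_group_R must lie between 0 and n_participants")
  }
  if (any(cfg$azimuths < -90 | cfg$azimuths > 90)) {
    al_stop("azimuths must lie in the frontal hemifield [-90, 90]")
  }
  if (cfg$reps < 1L) al_stop("reps must be >= 1")
  p <- cfg$p_dynamic
  if (any(p < 0 | p > 1)) al_stop("p_dynamic must lie in [0, 1]")
  if (length(p) > 1L && !all(c("R", "V") %in% names(p))) {
    al_stop("a per-condition p_dynamic must be named c(R = , V = )")
  }
  sds <- c(cfg$base_error_sd, cfg$dynamic_error_sd, cfg$divergence_sd_static,
           cfg$divergence_sd_dynamic, cfg$jitter_sd, cfg$latency_sdlog)
  if (any(sds < 0)) al_stop("all SDs must be >= 0")
  if (!all(c("R", "V") %in% names(cfg$base_error_sd))) {
    al_stop("base_error_sd must be named c(R = , V = )")
  }
  if (cfg$pivot_radius < 0) al_stop("pivot_radius must be >= 0")
  if (cfg$sample_rate <= 0) al_stop("sample_rate must be > 0")
  invisible(cfg)
}

p_dynamic_for <- function(cfg, condition) {
  p <- cfg$p_dynamic
  if (length(p) == 1L) unname(p[1]) else unname(p[[condition]])
}

yaw_to_quaternion <- function(yaw_deg) {
  # rightward-positive yaw = rotation about the vertical (y) axis by -yaw
  half <- -yaw_deg * pi / 360
  cbind(qw = cos(half), qx = 0, qy = sin(half), qz = 0)
}

#' Generate one synthetic trial
#'
#' Draws one trial under the behavioral model described in
#' [sim_config()] and returns its log record, 10 Hz trajectory, and the
#' generating truth. Randomness comes from the current RNG state; seed it
#' (or use [generate_dataset()], which seeds from the config) for
#' reproducibility.
#'
#' @param cfg A `"sim_config"`.
#' @param participant_id,group,condition,target_az Trial identity.
#' @param t_start Stimulus onset in seconds from session start.
#' @param trial_id Identifier to stamp on the record and trajectory.
#' @param coupled Is this participant's response coupled to divergence?
#' @return A list with `trial` (one-row data frame), `trajectory`
#'   (data frame with `nominal_rate` attribute), and `truth` (one-row
#'   data frame of the generating draws).
#' @export
generate_trial <- function(cfg, participant_id, group, condition, target_az,
                           t_start = 0, trial_id = "trial", coupled = FALSE) {
  dynamic <- stats::runif(1) < p_dynamic_for(cfg, condition)
  sdlog <- cfg$latency_sdlog
  meanlog <- log(cfg$latency_mean[group, condition]) - sdlog^2 / 2
  latency <- max(0.5, stats::rlnorm(1, meanlog, sdlog))

  divergence <- if (dynamic) {
    stats::rnorm(1, cfg$divergence_mean_dynamic, cfg$divergence_sd_dynamic)
  } else {
    stats::rnorm(1, cfg$divergence_mean_static, cfg$divergence_sd_static)
  }
  err_sd <- if (dynamic) cfg$dynamic_error_sd else cfg$base_error_sd[[condition]]
  signed_raw <- -cfg$undershoot_slope * target_az +
    cfg$rightward_bias[group, condition] +
    (if (coupled) cfg$coupling_gain * divergence else 0) +
    stats::rnorm(1, 0, err_sd)
  pointed <- round(wrap_angle(target_az + signed_raw))

  # trajectory ---------------------------------------------------------
  rate <- cfg$sample_rate
  s <- seq(0, floor(latency * rate)) / rate
  tau <- min(stats::runif(1, 0.3, 1.0), latency / 4)
  yaw_final <- wrap_angle(target_az - divergence)
  yaw <- yaw_final * (1 - exp(-s / tau))
  if (dynamic) {
    amp <- stats::runif(1, 10, 40)
    f_search <- stats::runif(1, 0.5, 1.5)
    yaw <- yaw + amp * exp(-s / tau) * sin(2 * pi * f_search * s)
  }
  sway <- vapply(1:3, function(axis) {
    a <- abs(stats::rnorm(1)) * cfg$jitter_sd
    f <- stats::runif(1, 0.1, 0.5)
    phi <- stats::runif(1, 0, 2 * pi)
    a * (sin(2 * pi * f * s + phi) - sin(phi))
  }, numeric(length(s)))
  if (length(s) == 1L) sway <- matrix(sway, nrow = 1L)
  if (dynamic) {
    th <- yaw * pi / 180
    pos <- cbind(cfg$pivot_radius * sin(th), 0,
                 cfg$pivot_radius * (1 - cos(th))) + sway
  } else {
    pos <- sway
  }
  quat <- yaw_to_quaternion(yaw)
  trajectory <- data.frame(t = t_start + s,
                           x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           qw = quat[, "qw"], qx = quat[, "qx"],
                           qy = quat[, "qy"], qz = quat[, "qz"])
  attr(trajectory, "nominal_rate") <- rate

  trial <- data.frame(trial_id = trial_id,
                      participant_id = participant_id,
                      group = group, condition = condition,
                      target_az = target_az, pointed_az = pointed,
                      t_onset = t_start, t_hit = t_start + latency,
                      trajectory_ref = trial_id,
                      stringsAsFactors = FALSE)
  truth <- data.frame(trial_id = trial_id, dynamic = dynamic,
                      divergence_drawn = divergence, err_sd = err_sd,
                      bias = cfg$rightward_bias[group, condition],
                      latency = latency, coupled = coupled,
                      stringsAsFactors = FALSE)
  list(trial = trial, trajectory = trajectory, truth = truth)
}

#' Generate a full synthetic study
#'
#' Every participant completes one randomly balanced block of
#' `length(azimuths) * reps` trials in each condition (each azimuth
#' appearing exactly `reps` times), in the order dictated by their group
#' (`G_R`: real first; `G_V`: virtual first). Group membership is a
#' seeded random assignment of `n_group_R` participants. All draws pass
#' through a single RNG stream seeded from `cfg$seed`, so output is
#' bitwise reproducible.
#'
#' @param cfg A `"sim_config"`.
#' @return A list with `trials` (data frame, one row per trial),
#'   `trajectories` (named list keyed by trial id), and `truth` (a list
#'   with the `config` and the per-trial generating draws).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- cfg$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  groups <- sample(c(rep("G_R", cfg$n_group_R), rep("G_V", n - cfg$n_group_R)))
  names(groups) <- ids
  gv_ids <- ids[groups == "G_V"]
  coupled_ids <- character(0)
  if (cfg$n_coupled > 0L && length(gv_ids) > 0L) {
    coupled_ids <- sample(gv_ids, min(cfg$n_coupled, length(gv_ids)))
  }

  trials_list <- list()
  truth_list <- list()
  trajectories <- list()
  for (pid in ids) {
    grp <- groups[[pid]]
    cond_order <- if (grp == "G_R") c("R", "V") else c("V", "R")
    cursor <- 0
    for (cond in cond_order) {
      targets <- sample(rep(cfg$azimuths, cfg$reps))
      for (i in seq_along(targets)) {
        tid <- sprintf("%s_%s_%03d", pid, cond, i)
        one <- generate_trial(cfg, pid, grp, cond, targets[i],
                              t_start = cursor, trial_id = tid,
                              coupled = pid %in% coupled_ids)
        trials_list[[tid]] <- one$trial
        truth_list[[tid]] <- one$truth
        trajectories[[tid]] <- one$trajectory
        cursor <- one$trial$t_hit + 1.0 # 1 s silent pause between trials
      }
    }
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL
  truth_df <- do.call(rbind, truth_list)
  rownames(truth_df) <- NULL
  list(trials = trials,
       trajectories = trajectories,
       truth = list(config = cfg,
                    groups = groups,
                    coupled_participants = coupled_ids,
                    per_trial = truth_df))
}

#' Write a synthetic study to disk as a fixture
#'
#' Serialises a generated dataset in the package's file formats:
#' `trials.csv` (trial log), `trajectories.csv` (long format), and
#' `truth.json` (the generating configuration and per-trial draws). The
#' files round-trip through [read_trial_log()] and
#' [read_trajectories()].
#'
#' @param cfg A `"sim_config"`.
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(cfg)
  paths <- c(trials = file.path(outdir, "trials.csv"),
             trajectories = file.path(outdir, "trajectories.csv"),
             truth = file.path(outdir, "truth.json"))
  utils::write.csv(ds$trials, paths["trials"], row.names = FALSE, quote = FALSE)
  long <- do.call(rbind, lapply(names(ds$trajectories), function(tid) {
    cbind(trial_id = tid, ds$trajectories[[tid]])
  }))
  utils::write.csv(long, paths["trajectories"], row.names = FALSE,
                   quote = FALSE)
  truth <- ds$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
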