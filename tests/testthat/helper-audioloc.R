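# Shared fixtures and independent oracles for the test suite.

# --- quaternion / rotation oracles (independent of the package's
# forward-vector route: these go through the explicit 3x3 matrix) -------

rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

yaw_oracle <- function(q) {
  v <- rotmat_from_quat(q) %*% c(0, 0, -1)
  horiz <- sqrt(v[1]^2 + v[3]^2)
  if (horiz < 1e-9) return(NA_real_)
  atan2(v[1], -v[3]) * 180 / pi
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# rotation about the vertical (+y) axis by `angle` radians, right-handed
quat_about_y <- function(angle) {
  c(cos(angle / 2), 0, sin(angle / 2), 0)
}

# --- small trajectory builder -----------------------------------------

make_traj <- function(t, pos = NULL, yaw_deg = NULL, rate = 10) {
  n <- length(t)
  if (is.null(pos)) pos <- matrix(0, n, 3)
  if (is.null(yaw_deg)) yaw_deg <- rep(0, n)
  half <- -yaw_deg * pi / 360
  tr <- data.frame(t = t, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   qw = cos(half), qx = 0, qy = sin(half), qz = 0)
  attr(tr, "nominal_rate") <- rate
  tr
}

# --- cached default synthetic study (generated once per test run) ------

.audioloc_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.audioloc_cache$study)) {
    ds <- generate_dataset(sim_config())
    metrics <- flag_outliers(compute_trial_metrics(ds$trials,
                                                   ds$trajectories))
    .audioloc_cache$study <- list(dataset = ds, metrics = metrics)
  }
  .audioloc_cache$study
}

# Welch one-way ANOVA computed from the textbook formulas (oracle).
welch_anova_oracle <- function(samples) {
  k <- length(samples)
  n <- lengths(samples)
  m <- vapply(samples, mean, numeric(1))
  v <- vapply(samples, stats::var, numeric(1))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  list(F = A / B, df1 = k - 1, df2 = (k^2 - 1) / (3 * lambda))
}
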