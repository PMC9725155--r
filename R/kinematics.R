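# Head-movement kinematics: yaw extraction from orientation quaternions,
# head divergence, and cumulative head path length.
#
# Coordinate conventions (package-wide): right-handed frame, y up, the
# listener sits at the origin facing -z at trial start. Azimuths and yaw
# angles are measured in the horizontal x-z plane, 0 degrees straight
# ahead, positive to the listener's RIGHT (+x), wrapped into (-180, 180].

#' Wrap an angle into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(190, -345, 180, 360))
#' @export
wrap_angle <- function(x) {
  r <- x %% 360
  ifelse(r > 180, r - 360, r)
}

#' Extract horizontal yaw from an orientation quaternion
#'
#' Rotates the frame's forward unit vector (0, 0, -1) by the quaternion,
#' projects the result onto the horizontal plane and returns the signed
#' angle from straight ahead, positive rightward. This projection route
#' avoids the order ambiguity of Euler decompositions.
#'
#' @param quat Numeric length-4 unit quaternion `(w, x, y, z)`; its norm
#'   must be within `1e-6` of 1 (use [read_trajectories()] to renormalize
#'   raw tracker output).
#' @return Yaw angle in degrees in (-180, 180]. Orientations whose forward
#'   vector points within numerical precision of straight up or down have
#'   no defined yaw and raise a degenerate-orientation error; callers
#'   processing streams may carry the last valid yaw forward.
#' @examples
#' quaternion_to_yaw(c(1, 0, 0, 0)) # identity orientation -> 0
#' @export
quaternion_to_yaw <- function(quat) {
  if (length(quat) != 4L || !is.numeric(quat) || anyNA(quat)) {
    al_stop("'quat' must be a numeric length-4 (w, x, y, z) quaternion")
  }
  nrm <- sqrt(sum(quat^2))
  if (abs(nrm - 1) > 1e-6) {
    al_stop(sprintf("quaternion norm %.8f is not unit (tolerance 1e-6)", nrm))
  }
  v <- rotate_vector(quat, c(0, 0, -1))
  horiz <- sqrt(v[1]^2 + v[3]^2)
  if (horiz < 1e-9) {
    al_stop("forward vector is vertical: yaw undefined for this orientation",
            class = "degenerate")
  }
  atan2(v[1], -v[3]) * 180 / pi
}

# Rotate a 3-vector by a unit quaternion (w,x,y,z):
# v' = v + 2 qv x (qv x v + w v)
rotate_vector <- function(quat, v) {
  qv <- quat[2:4]
  t2 <- 2 * cross3(qv, v)
  v + quat[1] * t2 + cross3(qv, t2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Head divergence: angular miss of the head relative to the target
#'
#' The circular difference `target_az - yaw`, wrapped into (-180, 180].
#' Zero means the head points exactly at the sound source at response
#' time; the sign follows the rightward-positive azimuth convention.
#'
#' @param target_az Target azimuth in degrees.
#' @param yaw Head yaw in degrees (e.g. from [yaw_at_hit()]).
#' @return Divergence in degrees in (-180, 180]. Vectorized.
#' @examples
#' head_divergence(30, 30)    # head on target -> 0
#' head_divergence(-170, 175) # wraps to 15, not -345
#' @export
head_divergence <- function(target_az, yaw) {
  if (!all(is.finite(target_az)) || !all(is.finite(yaw))) {
    al_stop("'target_az' and 'yaw' must be finite")
  }
  wrap_angle(target_az - yaw)
}

#' Head yaw at the moment of response
#'
#' Returns the yaw of the trajectory sample nearest in time to `t_hit`
#' (ties break to the earlier sample). No interpolation is attempted: at a
#' 10 Hz tracker rate any interpolation model would be unverifiable.
#'
#' @param traj A head trajectory as returned by [read_trajectories()]: a
#'   data frame with columns `t, x, y, z, qw, qx, qy, qz` and a
#'   `nominal_rate` attribute (Hz, default 10).
#' @param t_hit Response time in seconds; must lie within the sampled
#'   window padded by one nominal sample period on each side.
#' @return Yaw in degrees at the nearest sample.
#' @export
yaw_at_hit <- function(traj, t_hit) {
  if (is.null(traj) || nrow(traj) == 0L) {
    al_stop("empty trajectory: cannot evaluate yaw")
  }
  rate <- attr(traj, "nominal_rate") %||% 10
  pad <- 1 / rate
  ts <- traj$t
  if (t_hit < ts[1] - pad || t_hit > ts[length(ts)] + pad) {
    al_stop(sprintf(
      "t_hit = %.3f s outside sampled window [%.3f, %.3f] padded by %.3f s",
      t_hit, ts[1], ts[length(ts)], pad))
  }
  i <- which.min(abs(ts - t_hit)) # which.min takes the first (earlier) tie
  quaternion_to_yaw(c(traj$qw[i], traj$qx[i], traj$qy[i], traj$qz[i]))
}

#' Cumulative head path length over a trial
#'
#' Sum of Euclidean distances between consecutive head positions over the
#' samples falling in `[t_onset, t_hit]` — the head-dynamism measure.
#' Positions are used raw (no smoothing); `min_step` optionally drops
#' sub-threshold displacements if raw tracker jitter must be suppressed.
#'
#' @param traj Trajectory data frame (see [yaw_at_hit()]).
#' @param t_onset,t_hit Stimulus onset and response times in seconds.
#' @param min_step Minimum displacement in meters for a segment to count
#'   (default 0: full fidelity to the raw track).
#' @return Path length in meters (0 if fewer than 2 samples fall in the
#'   window).
#' @export
head_distance <- function(traj, t_onset, t_hit, min_step = 0) {
  if (is.null(traj) || nrow(traj) == 0L) {
    al_stop("empty trajectory: cannot compute head distance")
  }
  if (t_onset >= t_hit) {
    al_stop("t_onset must be strictly before t_hit")
  }
  sel <- traj$t >= t_onset & traj$t <= t_hit
  if (sum(sel) < 2L) {
    return(0)
  }
  p <- cbind(traj$x[sel], traj$y[sel], traj$z[sel])
  seg <- sqrt(rowSums(diff(p)^2))
  if (min_step > 0) seg <- seg[seg >= min_step]
  sum(seg)
}
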