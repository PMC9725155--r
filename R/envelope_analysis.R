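# Head-distance-versus-error envelope analysis: per-bin upper confidence
# bounds, their linear and logarithmic regressions, the quadrant-partition
# frontier, and the quartile-split divergence comparison. These are the
# statistics that make the "triangular" coupling between head movement and
# localization accuracy quantitative: large head distance co-occurs only
# with small unsigned error.

#' Per-bin upper confidence bounds of head distance
#'
#' Bins (unsigned error, head distance) pairs into fixed-width error bins
#' (see [bin_by_degree()]) and computes, per bin, `mean(h) + k_sd * sd(h)`
#' with the sample SD. `k_sd = 1.96` gives the two-sided-normal 95% upper
#' bound; `k_sd = 3` the 99.7% one. Bins holding fewer than 2 points have
#' no sample SD and are excluded (and reported in `excluded`).
#'
#' @param eps Unsigned errors in degrees.
#' @param h Head distances in meters (same length as `eps`).
#' @param k_sd SD multiplier of the bound.
#' @param bin_width Bin width in degrees (default 1).
#' @return A list with `bin_centers` (ascending), `upper_bounds`,
#'   `counts`, and `excluded` (centers of the dropped thin bins).
#' @export
bin_upper_bounds <- function(eps, h, k_sd, bin_width = 1) {
  if (length(eps) != length(h)) al_stop("eps and h must have equal length")
  if (length(eps) < 1L) al_stop("need at least one (eps, h) pair")
  if (!is.numeric(k_sd) || k_sd < 0) al_stop("k_sd must be >= 0")
  centers_all <- bin_width * floor(eps / bin_width + 0.5)
  centers <- sort(unique(centers_all))
  keep <- logical(length(centers))
  bounds <- numeric(length(centers))
  counts <- integer(length(centers))
  for (i in seq_along(centers)) {
    hv <- h[centers_all == centers[i]]
    counts[i] <- length(hv)
    if (length(hv) >= 2L) {
      keep[i] <- TRUE
      bounds[i] <- mean(hv) + k_sd * stats::sd(hv)
    }
  }
  if (!any(keep)) {
    al_stop("all bins have fewer than 2 points: no bounds can be formed",
            "analysis")
  }
  list(bin_centers = centers[keep],
       upper_bounds = bounds[keep],
       counts = counts[keep],
       excluded = centers[!keep])
}

#' Linear regression of an upper envelope
#'
#' Unweighted OLS of the per-bin upper bounds on the bin centers,
#' summarising how the reachable head distance shrinks with error (the
#' envelope model `h ~ m * eps + q`). A count-weighted fit is available
#' via `weights`.
#'
#' @param bin_centers,upper_bounds Output of [bin_upper_bounds()]
#'   (at least 3 bins).
#' @param weights Optional per-bin weights (e.g. bin counts).
#' @return A `"regression_fit"` with slope `m`, intercept `q` and r-squared.
#' @export
fit_linear_envelope <- function(bin_centers, upper_bounds, weights = NULL) {
  if (length(bin_centers) != length(upper_bounds)) {
    al_stop("bin_centers and upper_bounds must have equal length")
  }
  if (length(bin_centers) < 3L) al_stop("need at least 3 bins")
  if (is.null(weights)) {
    ols_fit(bin_centers, upper_bounds)
  } else {
    fit <- stats::lm(upper_bounds ~ bin_centers, weights = weights)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    new_regression_fit(unname(stats::coef(fit)[2]),
                       unname(stats::coef(fit)[1]),
                       r2,
                       length(upper_bounds))
  }
}

#' Logarithmic regression of an upper envelope
#'
#' Fits the log-transformed envelope model
#' `h ~ A * log(max_error + 1 - eps) + B` by OLS on the transformed
#' predictor (natural log). `max_error` is the maximum unsigned error of
#' the data set being described, so the predictor stays positive up to
#' and including `eps = max_error` (where it is `log(1) = 0`).
#'
#' @param bin_centers,upper_bounds Output of [bin_upper_bounds()]
#'   (at least 3 bins).
#' @param max_error Maximum unsigned error in degrees; every bin center
#'   must be `<= max_error`.
#' @return A list of class `"log_envelope_fit"` with `A`, `B`,
#'   `r_squared`, `max_error` and `n_points`.
#' @export
fit_log_envelope <- function(bin_centers, upper_bounds, max_error) {
  if (length(bin_centers) != length(upper_bounds)) {
    al_stop("bin_centers and upper_bounds must have equal length")
  }
  if (length(bin_centers) < 3L) al_stop("need at least 3 bins")
  if (any(bin_centers > max_error)) {
    al_stop("every bin center must be <= max_error (log of non-positive argument)")
  }
  x <- log(max_error + 1 - bin_centers)
  fit <- ols_fit(x, upper_bounds)
  structure(list(A = fit$slope, B = fit$intercept,
                 r_squared = fit$r_squared,
                 max_error = max_error, n_points = fit$n_points),
            class = "log_envelope_fit")
}

#' @export
print.log_envelope_fit <- function(x, ...) {
  cat(sprintf(
    "log envelope fit: A = %.4g, B = %.4g, r^2 = %.3f (max_error = %g, n = %d)\n",
    x$A, x$B, x$r_squared, x$max_error, x$n_points))
  invisible(x)
}

#' Quadrant-partition frontier
#'
#' Sweeps candidate corners over the sorted unique unsigned errors. For
#' each corner abscissa `eps0`, the ordinate `h0` is chosen as the k-th
#' largest head distance among trials with `eps >= eps0`, where
#' `k = round(fraction * N)` (at least 1). The closed upper-right
#' quadrant `{eps >= eps0, h >= h0}` then contains exactly `k` points
#' when the distances in that tail are distinct; with ties it contains
#' the smallest attainable count `>= k`. The sweep stops when fewer than
#' `k` points remain to the right. `h0` is non-increasing in `eps0`.
#'
#' @param eps Unsigned errors in degrees.
#' @param h Head distances in meters.
#' @param fraction Target fraction of points per quadrant (default 0.05);
#'   `length(eps) * fraction` must be at least 1.
#' @return A list of class `"quadrant_curve"` with `fraction`, `k`,
#'   `n_total`, and `points` (a data frame of `eps0`, `h0` in ascending
#'   `eps0`).
#' @export
quadrant_curve <- function(eps, h, fraction = 0.05) {
  if (length(eps) != length(h)) al_stop("eps and h must have equal length")
  n <- length(eps)
  if (n * fraction < 1) {
    al_stop("fraction * N < 1: no quadrant can hold the requested share")
  }
  k <- max(1L, as.integer(round(fraction * n)))
  corners <- sort(unique(eps))
  eps0 <- numeric(0)
  h0 <- numeric(0)
  for (e0 in corners) {
    tail_h <- h[eps >= e0]
    if (length(tail_h) < k) break
    eps0 <- c(eps0, e0)
    h0 <- c(h0, sort(tail_h, decreasing = TRUE)[k])
  }
  structure(list(fraction = fraction, k = k, n_total = n,
                 points = data.frame(eps0 = eps0, h0 = h0)),
            class = "quadrant_curve")
}

#' @export
print.quadrant_curve <- function(x, ...) {
  cat(sprintf(
    "quadrant-partition curve: %d corners, k = %d of N = %d (fraction %.3g)\n",
    nrow(x$points), x$k, x$n_total, x$fraction))
  invisible(x)
}

# Frontier height at given eps values for the supported frontier objects.
frontier_height <- function(frontier, eps) {
  if (inherits(frontier, "quadrant_curve")) {
    pts <- frontier$points
    # step frontier: the corner with the largest eps0 <= eps governs;
    # left of the first corner the frontier is flat at its first height.
    idx <- findInterval(eps, pts$eps0)
    idx[idx < 1L] <- 1L
    pts$h0[idx]
  } else if (inherits(frontier, "regression_fit")) {
    frontier$intercept + frontier$slope * eps
  } else if (inherits(frontier, "log_envelope_fit")) {
    arg <- frontier$max_error + 1 - eps
    ifelse(arg > 0, frontier$A * log(arg) + frontier$B, -Inf)
  } else {
    al_stop("unsupported frontier object", "not_implemented")
  }
}

#' Fraction of points strictly above a frontier
#'
#' The sufficiency diagnostic: how often do trials combine large head
#' distance with large error, i.e. lie strictly above the frontier? For a
#' triangular data set this proportion is near zero for its own fitted
#' envelope.
#'
#' @param eps,h The data points.
#' @param frontier A `"quadrant_curve"`, `"regression_fit"` (linear
#'   envelope) or `"log_envelope_fit"`.
#' @return Proportion in `[0, 1]`.
#' @export
quadrant_emptiness <- function(eps, h, frontier) {
  if (length(eps) != length(h)) al_stop("eps and h must have equal length")
  if (length(eps) == 0L) return(0)
  mean(h > frontier_height(frontier, eps))
}

#' Quartile split of head divergence by head distance
#'
#' Splits trials at the third quartile of head distance (75th percentile,
#' linear interpolation between order statistics) and compares the head
#' divergence of high-movement trials (above Q3) with the rest. If
#' high-movement trials end with the head better aimed at the source,
#' both the absolute mean and the SD of their divergence shrink.
#'
#' @param metrics Metrics data frame with `head_distance` and
#'   `head_divergence` columns (at least 8 trials).
#' @param exclude_outliers Drop flagged trials first (default `TRUE`).
#' @return A list with `q3` (meters), `below` and `above` summaries
#'   (`n`, `mean`, `sd` of divergence), `mean_shift_pct`
#'   (`100 * (|mean_below| - |mean_above|) / |mean_below|`), and
#'   `sd_reduction_pct` (`100 * (sd_below - sd_above) / sd_below`).
#' @export
quartile_split_divergence <- function(metrics, exclude_outliers = TRUE) {
  if (exclude_outliers && "is_outlier" %in% names(metrics)) {
    metrics <- metrics[!metrics$is_outlier, , drop = FALSE]
  }
  if (nrow(metrics) < 8L) al_stop("need at least 8 trials for a quartile split")
  hd <- metrics$head_distance
  dv <- metrics$head_divergence
  q3 <- stats::quantile(hd, 0.75, type = 7, names = FALSE)
  above <- dv[hd > q3]
  below <- dv[hd <= q3]
  if (length(above) < 2L || length(below) < 2L) {
    al_stop("degenerate split: one side of the third quartile is (nearly) empty",
            "analysis")
  }
  mb <- mean(below); ma <- mean(above)
  sb <- stats::sd(below); sa <- stats::sd(above)
  list(q3 = q3,
       below = list(n = length(below), mean = mb, sd = sb),
       above = list(n = length(above), mean = ma, sd = sa),
       mean_shift_pct = 100 * (abs(mb) - abs(ma)) / abs(mb),
       sd_reduction_pct = 100 * (sb - sa) / sb)
}
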