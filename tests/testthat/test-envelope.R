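test_that("per-bin upper bounds are mean + k SD, thin bins excluded", {
  # one bin: h = {0.1, 0.3}, k = 3 -> 0.2 + 3 * 0.1414
  bb <- bin_upper_bounds(c(10.2, 9.8), c(0.1, 0.3), k_sd = 3)
  expect_equal(bb$bin_centers, 10)
  expect_equal(bb$upper_bounds, 0.2 + 3 * sd(c(0.1, 0.3)), tolerance = 1e-12)

  # constant h: SD 0, bound equals the constant
  bb2 <- bin_upper_bounds(c(5, 5.2), c(0.25, 0.25), k_sd = 3)
  expect_equal(bb2$upper_bounds, 0.25)

  # k = 0: bounds are the bin means
  eps <- c(1, 1.2, 2, 2.3)
  h <- c(0.1, 0.2, 0.3, 0.5)
  bb3 <- bin_upper_bounds(eps, h, k_sd = 0)
  expect_equal(bb3$upper_bounds, c(0.15, 0.4))

  # singleton bins are excluded and reported
  bb4 <- bin_upper_bounds(c(1, 1.1, 5), c(0.1, 0.2, 0.9), k_sd = 2)
  expect_equal(bb4$excluded, 5)
  expect_equal(bb4$bin_centers, 1)

  expect_error(bin_upper_bounds(c(1, 5), c(0.1, 0.9), k_sd = 2),
               class = "audioloc_analysis_error")

  # a wider level never yields a lower bound, bin-wise
  set.seed(41)
  e <- runif(400, 0, 20)
  hh <- runif(400, 0, 0.5)
  b95 <- bin_upper_bounds(e, hh, k_sd = 1.96)
  b997 <- bin_upper_bounds(e, hh, k_sd = 3)
  expect_true(all(b997$upper_bounds >= b95$upper_bounds))
})

test_that("envelope regressions recover generating lines exactly", {
  centers <- 0:25
  lin <- fit_linear_envelope(centers, 2.5 - 0.1 * centers)
  expect_equal(lin$slope, -0.1, tolerance = 1e-12)
  expect_equal(lin$intercept, 2.5, tolerance = 1e-12)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)

  flat <- fit_linear_envelope(centers, rep(0.3, 26))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  max_err <- 25
  lf <- fit_log_envelope(centers, 0.2 * log(max_err + 1 - centers) + 0.05,
                         max_error = max_err)
  expect_equal(lf$A, 0.2, tolerance = 1e-12)
  expect_equal(lf$B, 0.05, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)
  # the last bin sits at eps = max_error, predictor log(1) = 0: still defined
  expect_true(is.finite(lf$A))

  expect_error(fit_log_envelope(c(0, 1, 30), c(1, 1, 1), max_error = 25),
               class = "audioloc_validation_error")
  expect_error(fit_linear_envelope(c(0, 1), c(1, 2)),
               class = "audioloc_validation_error")
})

test_that("quadrant frontier holds exactly k points per closed quadrant", {
  set.seed(42)
  # k = 1: the frontier is the running max of the error tail
  e20 <- runif(20, 0, 10)
  h20 <- runif(20)
  qc <- quadrant_curve(e20, h20, fraction = 0.05)
  expect_equal(qc$k, 1L)
  for (i in seq_len(nrow(qc$points))) {
    expect_equal(qc$points$h0[i], max(h20[e20 >= qc$points$eps0[i]]))
  }
  expect_true(all(diff(qc$points$h0) <= 0))

  # ties: all h equal gives a flat frontier with count >= k
  qt_ <- quadrant_curve(rep(1:10, each = 4), rep(0.2, 40), fraction = 0.1)
  expect_true(all(qt_$points$h0 == 0.2))
  for (i in seq_len(nrow(qt_$points))) {
    n_in <- sum(rep(1:10, each = 4) >= qt_$points$eps0[i])
    expect_gte(n_in, qt_$k)
  }

  expect_error(quadrant_curve(runif(10), runif(10), fraction = 0.05),
               class = "audioloc_validation_error")
})

test_that("points rarely exceed their own fitted upper envelope", {
  set.seed(43)
  # triangular data: h uniform under a shrinking ceiling c - s * eps
  eps <- runif(4000, 0, 20)
  h <- runif(4000, 0, 0.44 - 0.016 * eps)
  bb <- bin_upper_bounds(eps, h, k_sd = 3)
  lin <- fit_linear_envelope(bb$bin_centers, bb$upper_bounds)
  expect_lt(quadrant_emptiness(eps, h, lin), 0.01)
  expect_equal(quadrant_emptiness(eps, h * 0 + 10, lin), 1) # all above
  expect_equal(quadrant_emptiness(eps, h * 0, lin), 0)      # all below

  qc <- quadrant_curve(eps, h, fraction = 0.05)
  above <- quadrant_emptiness(eps, h, qc)
  expect_gte(above, 0.05) # at least the rightmost quadrant's share is above
  expect_lte(above, 1)
})

test_that("linear envelope slope tracks the generating ceiling", {
  # ceiling c - s*eps with h uniform under it: the k-SD bound of a
  # uniform[0, b] is b * (1/2 + k/sqrt(12)), so the fitted slope targets
  # -s * (1/2 + 3/sqrt(12))
  s_true <- 0.016
  implied <- -s_true * (0.5 + 3 / sqrt(12))
  set.seed(44)
  # integer errors put every observation exactly at its bin center, so the
  # per-bin ceiling is constant and the implied slope is exact
  slopes <- replicate(25, {
    eps <- sample(0:20, 3000, replace = TRUE)
    h <- runif(3000, 0, 0.44 - s_true * eps)
    bb <- bin_upper_bounds(eps, h, k_sd = 3)
    fit_linear_envelope(bb$bin_centers, bb$upper_bounds)$slope
  })
  ci <- mean(slopes) + c(-1.96, 1.96) * sd(slopes) / sqrt(length(slopes))
  expect_gt(implied, ci[1])
  expect_lt(implied, ci[2])
  # r^2 stays in the regime seen for triangular data
  eps <- sample(0:20, 3000, replace = TRUE)
  h <- runif(3000, 0, 0.44 - s_true * eps)
  bb <- bin_upper_bounds(eps, h, k_sd = 3)
  expect_gt(fit_linear_envelope(bb$bin_centers, bb$upper_bounds)$r_squared,
            0.6)
  expect_gt(fit_log_envelope(bb$bin_centers, bb$upper_bounds,
                             max(eps))$r_squared, 0.6)
})

test_that("quartile split compares divergence above and below Q3 of distance", {
  m <- data.frame(
    head_distance = c(1, 2, 3, 4, 5, 6, 10, 11),
    head_divergence = c(-2, 2, 4, -2, 2, 4, -1, 1),
    is_outlier = FALSE
  )
  # Q3 of distance = 7 (linear interpolation), so {10, 11} sit above
  res <- quartile_split_divergence(m)
  expect_equal(res$q3, 7)
  expect_equal(res$above$n, 2)
  expect_equal(res$below$mean, 4 / 3, tolerance = 1e-12)
  expect_equal(res$above$mean, 0)
  expect_equal(res$mean_shift_pct, 100) # perfectly centered above Q3

  # both sides share mean 2 and SD sqrt(2): both percentages are 0
  m2 <- data.frame(
    head_distance = c(1, 2, 3, 4, 5, 6, 10, 11),
    head_divergence = c(0, 4, 3, 1, 2, 2, 1, 3),
    is_outlier = FALSE
  )
  res2 <- quartile_split_divergence(m2)
  expect_equal(res2$mean_shift_pct, 0, tolerance = 1e-9)
  expect_equal(res2$sd_reduction_pct, 0, tolerance = 1e-9)

  expect_error(quartile_split_divergence(m[1:5, ]),
               class = "audioloc_validation_error")
})
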