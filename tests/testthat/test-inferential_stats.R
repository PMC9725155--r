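test_that("Levene's test matches an ANOVA on absolute mean deviations", {
  # two samples with the same values: no variance difference at all
  s <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- levene_test(s)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(31)
  samples <- list(rnorm(15), rnorm(20, sd = 2), rnorm(12, sd = 0.5))
  res <- levene_test(samples)
  # oracle: one-way ANOVA on |x - group mean|
  z <- unlist(lapply(samples, function(x) abs(x - mean(x))))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  tab <- anova(aov(z ~ g))
  expect_equal(res$statistic, tab$`F value`[1], tolerance = 1e-9)
  expect_equal(res$p_value, tab$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(c(res$dof1, res$dof2), tab$Df)

  # clearly unequal variances are detected
  big <- levene_test(list(rnorm(500), rnorm(500, sd = 3)))
  expect_lt(big$p_value, 0.001)

  expect_error(levene_test(list(1, c(1, 2))),
               class = "audioloc_validation_error")
})

test_that("Welch ANOVA matches the Welch-Satterthwaite formulas; F = t^2 for 2 groups", {
  a <- c(5.1, 4.8, 5.5, 5.0, 4.2)
  res0 <- welch_t(a, a)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  set.seed(32)
  for (i in 1:20) {
    samples <- list(rnorm(sample(5:40, 1)),
                    rnorm(sample(5:40, 1), mean = 0.5, sd = 2),
                    rnorm(sample(5:40, 1), sd = 0.3))
    res <- welch_anova(samples)
    oracle <- welch_anova_oracle(samples)
    expect_equal(res$statistic, oracle$F, tolerance = 1e-9)
    expect_equal(res$dof1, oracle$df1)
    expect_equal(res$dof2, oracle$df2, tolerance = 1e-9)

    x <- rnorm(20); y <- rnorm(25, 0.3, 1.7)
    f2 <- welch_anova(list(x, y))
    t2 <- welch_t(x, y)
    expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-9)
    expect_equal(f2$p_value, t2$p_value, tolerance = 1e-9)
  }
})

test_that("Spearman is Pearson on average ranks, two-tailed", {
  x <- 1:10
  expect_equal(spearman_test(x, x^3)$statistic, 1)
  expect_equal(spearman_test(x, -x)$statistic, -1)

  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(20)
    y <- round(rnorm(20), 1) # rounding creates ties
    res <- spearman_test(x, y)
    expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  expect_error(spearman_test(1:4, 1:5), class = "audioloc_validation_error")
  expect_error(spearman_test(1:2, 1:2), class = "audioloc_validation_error")
})

test_that("Bonferroni caps at 1, is monotone, allows a declared family size", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(numeric(0)), numeric(0))
  p <- c(0.001, 0.02, 0.2, 0.9)
  adj <- bonferroni(p, m = 6)
  expect_true(all(diff(adj) >= 0)) # order-preserving
  expect_true(all(adj >= p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1),
               class = "audioloc_validation_error")
})

test_that("post-hoc power follows the noncentral t/F distributions", {
  t_res <- welch_t(rnorm(10), rnorm(10))
  expect_equal(posthoc_power(t_res, c(100, 100), effect = 0), 0.05,
               tolerance = 1e-12)
  expect_gt(posthoc_power(t_res, c(50, 50), effect = 5), 0.999)

  # Monte-Carlo oracle at d = 0.5, n = 100 per group
  set.seed(34)
  hits <- mean(replicate(2000, {
    t.test(rnorm(100), rnorm(100, mean = 0.5))$p.value < 0.05
  }))
  analytic <- posthoc_power(t_res, c(100, 100), effect = 0.5)
  expect_equal(analytic, hits, tolerance = 0.02)

  f_res <- anova_f(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_equal(posthoc_power(f_res, c(30, 30, 30), effect = 0), 0.05,
               tolerance = 1e-12)
  sp <- spearman_test(rnorm(10), rnorm(10))
  expect_error(posthoc_power(sp, c(10, 10), 0.5),
               class = "audioloc_not_implemented_error")
})

test_that("eccentricity regression fits the per-azimuth means", {
  az <- seq(-90, 90, by = 15)
  m <- do.call(rbind, lapply(az, function(a) {
    data.frame(participant_id = "P01", group = "G_V", condition = "V",
               target_az = a, signed_error = 0.4 * a + c(-1, 0, 1),
               stringsAsFactors = FALSE)
  }))
  fit <- eccentricity_regression(m, "signed_error")
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 13L)

  m$signed_error <- 2 # constant response: r^2 defined as 0
  flat <- eccentricity_regression(m, "signed_error")
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(
    eccentricity_regression(m[m$target_az %in% c(0, 15), ], "signed_error"),
    class = "audioloc_validation_error")
})

test_that("per-participant correlations flag strong divergence-error coupling", {
  set.seed(35)
  mk <- function(pid, div, err) {
    data.frame(trial_id = paste0(pid, seq_along(div)),
               participant_id = pid, group = "G_V", condition = "V",
               target_az = 0, signed_error = err,
               unsigned_error = abs(err), latency = 3,
               head_divergence = div, head_distance = 0.1,
               is_outlier = FALSE, stringsAsFactors = FALSE)
  }
  div1 <- rnorm(60, sd = 20)
  div2 <- rnorm(60, sd = 20)
  m <- rbind(mk("coupled", div1, div1 * 0.2),         # exact monotone link
             mk("independent", div2, rnorm(60, sd = 4)))
  res <- per_participant_spearman(m)
  expect_equal(nrow(res), 2)
  expect_equal(res$rho[res$participant_id == "coupled"], 1)
  expect_lt(abs(res$rho[res$participant_id == "independent"]), 0.3)
  expect_false(res$significant[res$participant_id == "independent"])
  expect_true(all(abs(res$mean_signed_norm) <= 1))
  expect_true(all(abs(res$mean_unsigned_norm) <= 1))
})
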