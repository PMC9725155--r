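make_trial_log <- function(n_targets = 13, reps = 5) {
  az <- rep(seq(-90, 90, by = 15)[seq_len(n_targets)], reps)
  n <- length(az)
  data.frame(
    trial_id = sprintf("T%03d", seq_len(n)),
    participant_id = "P01",
    group = "G_R",
    condition = rep(c("R", "V"), length.out = n),
    target_az = az,
    pointed_az = az + sample(-3:3, n, replace = TRUE),
    t_onset = seq(0, by = 5, length.out = n),
    t_hit = seq(0, by = 5, length.out = n) + 3.2,
    trajectory_ref = sprintf("T%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

test_that("trial logs round-trip and preserve row order", {
  set.seed(1)
  log <- make_trial_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(log, path, row.names = FALSE)
  got <- read_trial_log(path)
  expect_equal(nrow(got), 65)
  expect_identical(got$trial_id, log$trial_id)
  expect_equal(got$t_hit, log$t_hit, tolerance = 1e-9)

  # header-only file: empty log, no error
  write.csv(log[0, ], path, row.names = FALSE)
  expect_equal(nrow(read_trial_log(path)), 0)
})

test_that("trial log validation names the offending column or row", {
  set.seed(1)
  log <- make_trial_log()
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(log[setdiff(names(log), "pointed_az")], path, row.names = FALSE)
  expect_error(read_trial_log(path), "pointed_az",
               class = "audioloc_format_error")

  bad <- log; bad$target_az[7] <- 7 # not on the 15-degree grid
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trial_log(path), "row 7",
               class = "audioloc_validation_error")

  bad <- log; bad$t_hit[3] <- bad$t_onset[3]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trial_log(path), "t_hit",
               class = "audioloc_validation_error")

  bad <- log; bad$pointed_az[2] <- 12.5
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_trial_log(path), "integer",
               class = "audioloc_validation_error")
})

test_that("trajectories group by trial, validate time order and quaternions", {
  t <- seq(0, 2.9, by = 0.1)
  one <- data.frame(t = t, x = 0, y = 0, z = 0,
                    qw = 1, qx = 0, qy = 0, qz = 0)
  long <- rbind(cbind(trial_id = "A", one), cbind(trial_id = "B", one))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  got <- read_trajectories(path)
  expect_named(got, c("A", "B"))
  expect_equal(vapply(got, nrow, integer(1)), c(A = 30L, B = 30L))

  # mildly off-unit quaternions are renormalized ...
  long2 <- long
  long2$qw <- 1.0005
  write.csv(long2, path, row.names = FALSE)
  got2 <- read_trajectories(path)
  expect_equal(got2$A$qw, rep(1, 30), tolerance = 1e-12)

  # ... clearly corrupt ones are rejected
  long2$qw[1] <- 2
  write.csv(long2, path, row.names = FALSE)
  expect_error(read_trajectories(path), "norm",
               class = "audioloc_validation_error")

  long3 <- long
  long3$t[5] <- long3$t[4] # repeated timestamp
  write.csv(long3, path, row.names = FALSE)
  expect_error(read_trajectories(path), "increasing",
               class = "audioloc_validation_error")
})

test_that("metrics tables round-trip losslessly, flags as 0/1", {
  set.seed(42)
  metrics <- data.frame(
    trial_id = sprintf("T%02d", 1:10),
    participant_id = "P01", group = "G_V", condition = "V",
    target_az = rep(c(-30, 45), 5), pointed_az = rep(c(-28, 47), 5),
    signed_error = rnorm(10), unsigned_error = abs(rnorm(10)),
    latency = runif(10, 1, 5), head_divergence = rnorm(10, sd = 20),
    head_distance = runif(10, 0, 0.4),
    is_outlier = rep(c(TRUE, FALSE), 5),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(metrics, path)
  raw <- read.csv(path)
  expect_true(all(raw$is_outlier %in% c(0L, 1L)))
  got <- read_metrics_table(path)
  expect_identical(got$is_outlier, metrics$is_outlier)
  for (col in c("signed_error", "latency", "head_distance")) {
    expect_equal(got[[col]], metrics[[col]], tolerance = 1e-9)
  }

  write_metrics_table(metrics[0, ], path) # empty table: header only
  expect_equal(nrow(read_metrics_table(path)), 0)
})

test_that("study config validates and round-trips through YAML", {
  cfg <- study_config()
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$envelope_levels, c("95" = 1.96, "99.7" = 3))
  expect_error(study_config(bin_width = 0),
               class = "audioloc_validation_error")
  expect_error(study_config(quadrant_fraction = 1),
               class = "audioloc_validation_error")

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(outlier_k = 2.5, alpha = 0.01,
                        envelope_levels = list("90" = 1.645)), path)
  got <- read_study_config(path)
  expect_equal(got$outlier_k, 2.5)
  expect_equal(got$alpha, 0.01)
  expect_equal(got$envelope_levels, c("90" = 1.645))
  expect_equal(got$bin_width, 1) # untouched default

  yaml::write_yaml(list(not_a_key = 1), path)
  expect_error(read_study_config(path), class = "audioloc_format_error")
})
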