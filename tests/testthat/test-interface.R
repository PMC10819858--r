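write_imu_fixture <- function(path, dt = 0.0025, n = 3,
                              gyr_deg = TRUE) {
  df <- data.frame(time_s = (0:(n - 1)) * dt,
                   ax = seq(0.1, by = 0.1, length.out = n),
                   ay = rep(-1, n), az = rep(0.05, n),
                   gx = rep(10, n), gy = rep(-20, n), gz = rep(5, n))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

test_that("IMU CSV parsing converts units as declared", {
  path <- tempfile(fileext = ".csv")
  df <- write_imu_fixture(path)
  rec <- read_imu_csv(path, acc_units = "g", gyro_units = "deg_s")
  expect_equal(rec$acc[, 1], df$ax * 9.80665, tolerance = 1e-12)
  expect_equal(rec$gyr[, 2], rep(-20 * pi / 180, 3), tolerance = 1e-12)
  expect_equal(rec$rate_hz, 400, tolerance = 1e-6)
  rec_si <- read_imu_csv(path, acc_units = "m_s2", gyro_units = "rad_s")
  expect_equal(rec_si$acc[, 1], df$ax)
})

test_that("IMU CSV errors name the first bad row and missing columns", {
  path <- tempfile(fileext = ".csv")
  df <- write_imu_fixture(path, n = 5)
  df$time_s[4] <- df$time_s[4] + 0.01  # gap
  write.csv(df, path, row.names = FALSE)
  expect_error(read_imu_csv(path), "row 4")
  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_imu_csv(path), "missing columns: ax")
  expect_error(read_imu_csv(tempfile()), "not found")
})

test_that("out-of-range values trigger device-range warnings", {
  path <- tempfile(fileext = ".csv")
  df <- write_imu_fixture(path, n = 3)
  df$ax <- c(0, 200, 0)  # > 16 g in m/s^2? 200 m/s^2 > 156.9
  write.csv(df, path, row.names = FALSE)
  expect_warning(read_imu_csv(path), "16 g")
  df$ax <- 0; df$gx <- c(0, 40, 0)  # 40 rad/s > 2000 deg/s
  write.csv(df, path, row.names = FALSE)
  expect_warning(read_imu_csv(path), "2000 deg")
})

test_that("IMU recording round-trips through CSV at 6 significant digits", {
  trial <- short_trial(seed = 3, duration_s = 4)
  path <- tempfile(fileext = ".csv")
  write_imu_csv(trial$pair$shank, path)
  back <- read_imu_csv(path, rate_hz = 400)
  expect_equal(back$acc, trial$pair$shank$acc, tolerance = 1e-4)
  expect_equal(back$gyr, trial$pair$shank$gyr, tolerance = 1e-4)
})

test_that("reference CSV parsing validates its contract", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 0.005, 0.01), alpha_deg = c(20, 21, 22)),
            path, row.names = FALSE)
  ref <- read_reference_csv(path)
  expect_s3_class(ref, "angle_series")
  expect_equal(ref$alpha, c(20, 21, 22))
  writeLines("time_s,alpha_deg", path)
  expect_error(read_reference_csv(path), "empty")
  writeLines(c("time_s,alpha_deg", "0,a", "1,2"), path)
  expect_error(read_reference_csv(path), "non-numeric")
})

test_that("YAML configs map onto control parameters and reject unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("filter.kind: kf", "filter.lambda: 0.02", "filter.q: 0.005",
               "window.lo_pct: 35", "gate.halfwidth_pct: 6", "seed: 7",
               "io.gyro_units: deg_s"), path)
  cfg <- read_config(path)
  expect_equal(cfg$filter, "kf")
  expect_equal(cfg$control$lam, 0.02)
  expect_equal(cfg$control$q, 0.005)
  expect_equal(cfg$control$window_lo_pct, 35)
  expect_equal(cfg$control$gate_halfwidth_pct, 6)
  expect_equal(cfg$control$seed, 7)
  expect_equal(cfg$io$gyro_units, "deg_s")
  writeLines("not.a.key: 1", path)
  expect_error(read_config(path), "unknown config keys")
})

test_that("fits run without a reference and stay deterministic", {
  trial <- short_trial(seed = 3, duration_s = 10)
  fit <- kneeflex(trial$pair, alpha0 = trial$truth$alpha_true[1],
                  control = kneeflex_control(filter_cutoff_hz = 150))
  expect_null(fit$eval)
  expect_s3_class(fit, "kneeflex")
  fit2 <- kneeflex(trial$pair, alpha0 = trial$truth$alpha_true[1],
                   control = kneeflex_control(filter_cutoff_hz = 150))
  expect_identical(fit$angles$fused$alpha, fit2$angles$fused$alpha)
  expect_identical(coef(fit), coef(fit2))
  expect_warning(kneeflex(trial$pair), "initializing at 0")
})

test_that("fit methods expose the expected summaries", {
  trial <- short_trial(seed = 3, duration_s = 10)
  fit <- kneeflex(trial$pair, reference = trial$reference,
                  control = kneeflex_control(filter_cutoff_hz = 150))
  expect_output(print(fit), "Knee flexion fit")
  expect_output(print(summary(fit)), "RMSE")
  cf <- coef(fit)
  expect_true(all(c("phi1", "alpha_offset") %in% names(cf)))
  expect_s3_class(fitted(fit), "angle_series")
  res <- residuals(fit)
  expect_lt(sqrt(mean(res^2)), 1)
  # predict applies the stored calibration to new data from the same session
  trial2 <- simulate_running_trial(duration_s = 6, seed = 31,
                                   mounting = trial$truth$mounting,
                                   noise = noise_free(impacts = TRUE))
  fit2 <- predict(fit, trial2$pair, reference = trial2$reference)
  expect_lt(fit2$eval$rmse_deg, 2)
  path <- tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("angle series round-trip through their CSV dialect", {
  trial <- short_trial(seed = 3, duration_s = 4)
  s <- angle_series(trial$pair$t, trial$truth$alpha_true, "truth")
  path <- tempfile(fileext = ".csv")
  write_angle_csv(s, path)
  df <- read.csv(path)
  expect_equal(df$alpha_deg, trial$truth$alpha_true, tolerance = 1e-4)
  expect_equal(unique(df$source), "truth")
})
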