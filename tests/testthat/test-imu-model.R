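test_that("imu_recording enforces its invariants", {
  t <- (0:9) / 100
  m <- matrix(0, 10, 3)
  rec <- imu_recording(t, m, m, 100)
  expect_s3_class(rec, "imu_recording")
  expect_error(imu_recording(t[-1], m, m, 100), "equal length")
  expect_error(imu_recording(t + c(0, 1e-4, rep(0, 8)), m, m, 100),
               "non-uniform|increasing")
  bad <- m; bad[3, 2] <- NA
  expect_error(imu_recording(t, bad, m, 100), "finite")
  t2 <- (0:9) / 200
  expect_error(sensor_pair(imu_recording(t, m, m, 100),
                           imu_recording(t2, m, m, 200)), "rates differ")
})

test_that("constant knee harmonics give a constant angle", {
  kin <- simulate_gait_kinematics(duration_s = 3, rate_hz = 200,
                                  angle_harmonics = list(c0 = 30, harmonics = NULL))
  expect_equal(kin$alpha_deg, rep(30, length(kin$t)))
  expect_equal(kin$alpha_d, rep(0, length(kin$t)))
})

test_that("default preset range matches a dense-grid evaluation of the series", {
  ah <- knee_harmonics_running()
  # independent oracle: evaluate the Fourier series directly on a dense grid
  pg <- seq(0, 1, length.out = 20001)
  a <- rep(ah$c0, length(pg))
  for (k in seq_len(nrow(ah$harmonics)))
    a <- a + ah$harmonics[k, "amp"] * cos(2 * pi * k * pg + ah$harmonics[k, "phase"])
  kin <- simulate_gait_kinematics(duration_s = 10, cycle_hz = 1.4, rate_hz = 400)
  expect_lt(abs(min(kin$alpha_deg) - min(a)), 0.1)
  expect_lt(abs(max(kin$alpha_deg) - max(a)), 0.1)
  expect_gt(min(a), 0)
})

test_that("kinematics rejects bad inputs", {
  expect_error(simulate_gait_kinematics(duration_s = -1), "positive")
  expect_error(simulate_gait_kinematics(duration_s = 1, cycle_hz = 1.4),
               "two gait cycles")
  hyper <- list(c0 = 10, harmonics = cbind(amp = 40, phase = 0))
  expect_error(simulate_gait_kinematics(duration_s = 5, angle_harmonics = hyper),
               "hyperextension|negative")
})

test_that("same seed reproduces the simulation bitwise", {
  a <- simulate_running_trial(duration_s = 4, seed = 9)
  b <- simulate_running_trial(duration_s = 4, seed = 9)
  expect_identical(a$pair$shank$acc, b$pair$shank$acc)
  expect_identical(a$pair$thigh$gyr, b$pair$thigh$gyr)
  expect_identical(a$truth$j1_true, b$truth$j1_true)
})

test_that("static pose yields zero rates and gravity-magnitude accelerations", {
  kin <- simulate_gait_kinematics(duration_s = 3, rate_hz = 200,
                                  angle_harmonics = list(c0 = 30, harmonics = NULL),
                                  thigh_amp_deg = 0, hip_bounce_m = 0,
                                  hip_sway_m = 0)
  mnt <- list(shank = mounting_spec(rot_about(c(1, 1, 0), 15), c(0.03, -0.12, 0.02)),
              thigh = mounting_spec(rot_about(c(0, 1, 1), -10), c(0.04, 0.15, 0.03)))
  sim <- simulate_imu(kin, mnt, noise_free(impacts = FALSE), seed = 1)
  expect_equal(max(abs(sim$pair$shank$gyr)), 0)
  expect_equal(max(abs(sim$pair$thigh$gyr)), 0)
  nrm1 <- sqrt(rowSums(sim$pair$shank$acc^2))
  nrm2 <- sqrt(rowSums(sim$pair$thigh$acc^2))
  expect_lt(max(abs(nrm1 - 9.80665)), 1e-9)
  expect_lt(max(abs(nrm2 - 9.80665)), 1e-9)
})

test_that("noise-free signals satisfy the hinge constraint", {
  trial <- short_trial(seed = 3, duration_s = 6)
  tr <- trial$truth
  g1 <- trial$pair$shank$gyr; g2 <- trial$pair$thigh$gyr
  n1 <- sqrt(rowSums((g1[, c(2, 3, 1)] * rep(tr$j1_true[c(3, 1, 2)], each = nrow(g1)) -
                        g1[, c(3, 1, 2)] * rep(tr$j1_true[c(2, 3, 1)], each = nrow(g1)))^2))
  n2 <- sqrt(rowSums((g2[, c(2, 3, 1)] * rep(tr$j2_true[c(3, 1, 2)], each = nrow(g2)) -
                        g2[, c(3, 1, 2)] * rep(tr$j2_true[c(2, 3, 1)], each = nrow(g2)))^2))
  expect_lt(max(abs(n1 - n2)), 1e-9)
})

test_that("noise-free lever-arm residual vanishes at the true joint centres", {
  trial <- short_trial(seed = 4, duration_s = 6,
                       noise = noise_free(impacts = FALSE))
  tr <- trial$truth; pair <- trial$pair; kin <- tr$kin
  # exact angular accelerations isolate the rigid-body identity itself
  gd1 <- outer(kin$theta_sh_dd, tr$j1_true)
  gd2 <- outer(kin$theta_th_dd, tr$j2_true)
  c1 <- correct_acceleration(pair$shank$acc, pair$shank$gyr, gd1, tr$o1_true)
  c2 <- correct_acceleration(pair$thigh$acc, pair$thigh$gyr, gd2, tr$o2_true)
  expect_lt(max(abs(sqrt(rowSums(c1^2)) - sqrt(rowSums(c2^2)))), 1e-6)
  # with five-point-differenced rates the residual stays at the stencil's
  # truncation level
  gd1n <- angular_acceleration(pair$shank$gyr, 1 / 400)
  c1n <- correct_acceleration(pair$shank$acc, pair$shank$gyr, gd1n, tr$o1_true)
  expect_lt(max(abs(sqrt(rowSums(c1n^2)) - sqrt(rowSums(c2^2)))), 1e-3)
})

test_that("accelerometer angle is the true angle plus a mounting constant", {
  trial <- short_trial(seed = 4, duration_s = 6,
                       noise = noise_free(impacts = FALSE))
  tr <- trial$truth; pair <- trial$pair; kin <- tr$kin
  # analytic angular accelerations: exact inputs isolate the identity
  gd1 <- outer(kin$theta_sh_dd, tr$j1_true)
  gd2 <- outer(kin$theta_th_dd, tr$j2_true)
  c1 <- correct_acceleration(pair$shank$acc, pair$shank$gyr, gd1, tr$o1_true)
  c2 <- correct_acceleration(pair$thigh$acc, pair$thigh$gyr, gd2, tr$o2_true)
  # flexion-positive branch: both true axes flipped jointly
  cal <- truth_calibration(-tr$j1_true, -tr$j2_true, tr$o1_true, tr$o2_true)
  aa <- accel_angle(c1, c2, cal)
  ok <- aa$valid
  d <- kneeflex:::wrap_pm180(aa$alpha[ok] - aa$alpha[ok][1]) -
    (tr$alpha_true[ok] - tr$alpha_true[ok][1])
  expect_lt(diff(range(d)), 1e-6)
})

test_that("doubling the noise level doubles the measurement noise", {
  kin <- simulate_gait_kinematics(duration_s = 30, rate_hz = 400)
  mnt <- list(shank = mounting_spec(rot_about(c(1, 2, 1), 12), c(0.03, -0.12, 0.02)),
              thigh = mounting_spec(rot_about(c(2, 1, 1), 8), c(0.04, 0.15, 0.03)))
  clean <- simulate_imu(kin, mnt, noise_free(impacts = FALSE), seed = 2)
  n1 <- simulate_imu(kin, mnt, noise_params(gyro_sd = 0.02, gyro_bias = 0,
                                            accel_sd = 0.3, impact_amp = 1e-12),
                     seed = 2)
  n2 <- simulate_imu(kin, mnt, noise_params(gyro_sd = 0.04, gyro_bias = 0,
                                            accel_sd = 0.6, impact_amp = 1e-12),
                     seed = 2)
  r1 <- sd(n1$pair$shank$gyr - clean$pair$shank$gyr)
  r2 <- sd(n2$pair$shank$gyr - clean$pair$shank$gyr)
  expect_lt(abs(r2 / r1 - 2), 0.1)
  a1 <- sd(n1$pair$thigh$acc - clean$pair$thigh$acc)
  a2 <- sd(n2$pair$thigh$acc - clean$pair$thigh$acc)
  expect_lt(abs(a2 / a1 - 2), 0.1)
})

test_that("mounting_spec rejects non-orthonormal rotations", {
  expect_error(mounting_spec(matrix(1, 3, 3)), "orthonormal")
  R <- rot_about(c(0, 0, 1), 30); R[, 1] <- -R[, 1]  # det -1
  expect_error(mounting_spec(R), "orthonormal")
})

test_that("ground truth axes are unit and strikes are recorded", {
  trial <- short_trial(seed = 5, duration_s = 6)
  expect_lt(abs(sqrt(sum(trial$truth$j1_true^2)) - 1), 1e-12)
  expect_lt(abs(sqrt(sum(trial$truth$j2_true^2)) - 1), 1e-12)
  expect_true(all(diff(trial$truth$strike_indices_true) > 0))
  # strikes sit at integer multiples of the cycle period
  expect_equal(trial$truth$strike_indices_true,
               sort(unique(pmin(round(seq(0, 6, by = 1 / 1.4) * 400) + 1, 2401))))
})
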