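test_that("axis cost matches hand-computed values", {
  g <- matrix(rnorm(30), 10, 3)
  expect_equal(axis_cost(0.3, 1.1, 0.3, 1.1, g, g), 0)
  # g1 = (1,0,0) with j = z (phi = pi/2): |g1 x j| = 1;
  # g2 = (0,2,0) with j = z: |g2 x j| = 2  ->  (1 - 2)^2 = 1
  expect_equal(axis_cost(pi / 2, 0, pi / 2, 0,
                         matrix(c(1, 0, 0), 1), matrix(c(0, 2, 0), 1)), 1)
  expect_error(axis_cost(0, 0, 0, 0, g[0, ], g[0, ]), "non-empty")
})

test_that("axis cost is invariant under sign flips of either axis", {
  set.seed(1)
  g1 <- matrix(rnorm(60), 20, 3); g2 <- matrix(rnorm(60), 20, 3)
  p <- c(0.4, -1.2, -0.2, 2.2)
  flip <- function(phi, theta) c(-phi, theta + pi)  # j -> -j
  base <- axis_cost(p[1], p[2], p[3], p[4], g1, g2)
  f1 <- flip(p[1], p[2]); f2 <- flip(p[3], p[4])
  expect_equal(axis_cost(f1[1], f1[2], p[3], p[4], g1, g2), base)
  expect_equal(axis_cost(p[1], p[2], f2[1], f2[2], g1, g2), base)
})

test_that("joint axes are recovered from noise-free running data", {
  trial <- short_trial(seed = 3, duration_s = 10)
  pair <- trial$pair; tr <- trial$truth
  ev <- build_masks(gait_phase(tr$strike_indices_true, pair$n))
  win <- which(ev$opt_mask)
  axes <- estimate_joint_axes(pair$shank$gyr[win, ], pair$thigh$gyr[win, ],
                              seed = 1)
  expect_lt(angle_between_deg(axes$j1, tr$j1_true), 0.5)
  expect_lt(angle_between_deg(axes$j2, tr$j2_true), 0.5)
  # optimality probe: no random parameter draw does better
  set.seed(7)
  probes <- replicate(100, {
    p <- c(runif(1, -pi / 2, pi / 2), runif(1, -pi, pi),
           runif(1, -pi / 2, pi / 2), runif(1, -pi, pi))
    axis_cost(p[1], p[2], p[3], p[4],
              pair$shank$gyr[win, ], pair$thigh$gyr[win, ])
  })
  expect_true(all(axes$final_cost <= probes + 1e-12))
})

test_that("axis recovery degrades gracefully under gyroscope noise", {
  trial <- simulate_running_trial(duration_s = 10, seed = 21,
                                  noise = noise_params(gyro_sd = 0.02,
                                                       gyro_bias = 0,
                                                       accel_sd = 0))
  pair <- trial$pair; tr <- trial$truth
  ev <- build_masks(gait_phase(tr$strike_indices_true, pair$n))
  win <- which(ev$opt_mask)
  axes <- estimate_joint_axes(pair$shank$gyr[win, ], pair$thigh$gyr[win, ],
                              seed = 1)
  expect_lt(angle_between_deg(axes$j1, tr$j1_true), 3)
  expect_lt(angle_between_deg(axes$j2, tr$j2_true), 3)
})

test_that("lever-arm term reproduces closed-form rigid-body accelerations", {
  expect_equal(rotational_acc_term(c(1, 2, 3), c(4, 5, 6), c(0, 0, 0)),
               c(0, 0, 0))
  # pure spin about z, point at radius r on x: centripetal -w^2 r x
  w <- 3; r <- 0.2
  expect_equal(rotational_acc_term(c(0, 0, w), c(0, 0, 0), c(r, 0, 0)),
               c(-w^2 * r, 0, 0))
  # pure angular acceleration about z: tangential beta r y
  b <- 5
  expect_equal(rotational_acc_term(c(0, 0, 0), c(0, 0, b), c(r, 0, 0)),
               c(0, b * r, 0))
})

test_that("centre cost matches limiting cases", {
  a <- matrix(rnorm(15), 5, 3)
  z <- matrix(0, 5, 3)
  expect_equal(center_cost(c(1, 2, 3) / 10, c(1, 2, 3) / 10, a, a, z, z, z, z), 0)
  a1 <- matrix(c(3, 0, 0), 1); a2 <- matrix(c(0, 4, 0), 1)
  z1 <- matrix(0, 1, 3)
  expect_equal(center_cost(rnorm(3), rnorm(3), a1, a2, z1, z1, z1, z1),
               (3 - 4)^2)
  expect_error(center_cost(rep(0, 3), rep(0, 3), a[0, ], a[0, ],
                           z[0, ], z[0, ], z[0, ], z[0, ]), "non-empty")
})

test_that("joint centres are recovered orthogonally to the axis", {
  trial <- short_trial(seed = 3, duration_s = 10)
  pair <- trial$pair; tr <- trial$truth
  ev <- build_masks(gait_phase(tr$strike_indices_true, pair$n))
  win <- which(ev$opt_mask); win <- win[win > 2 & win < pair$n - 1]
  # transparent passband: verifies the estimator algebra itself
  co <- 150
  a1f <- zero_lag_lowpass(pair$shank$acc, 400, co)
  a2f <- zero_lag_lowpass(pair$thigh$acc, 400, co)
  g1f <- zero_lag_lowpass(pair$shank$gyr, 400, co)
  g2f <- zero_lag_lowpass(pair$thigh$gyr, 400, co)
  gd1 <- angular_acceleration(g1f, 1 / 400)
  gd2 <- angular_acceleration(g2f, 1 / 400)
  W <- function(M) M[win, , drop = FALSE]
  cen <- estimate_joint_centers(W(a1f), W(a2f), W(g1f), W(g2f),
                                W(gd1), W(gd2), tr$j1_true, tr$j2_true,
                                seed = 2)
  e1 <- perp_component(cen$o1, tr$j1_true) - perp_component(tr$o1_true, tr$j1_true)
  e2 <- perp_component(cen$o2, tr$j2_true) - perp_component(tr$o2_true, tr$j2_true)
  expect_lt(sqrt(sum(e1^2)), 0.005)
  expect_lt(sqrt(sum(e2^2)), 0.005)
  # axial-component removal invariant
  expect_lt(abs(sum(cen$o1 * tr$j1_true) + sum(cen$o2 * tr$j2_true)), 1e-9)
  # the optimum is at least as good as the truth
  truth_cost <- center_cost(tr$o1_true, tr$o2_true, W(a1f), W(a2f),
                            W(g1f), W(g2f), W(gd1), W(gd2))
  expect_lte(cen$final_cost, truth_cost + 1e-9)
})

test_that("acceleration correction is the identity at zero lever and linear in o", {
  a <- matrix(rnorm(30), 10, 3)
  g <- matrix(rnorm(30), 10, 3)
  gd <- matrix(rnorm(30), 10, 3)
  expect_equal(correct_acceleration(a, g, gd, c(0, 0, 0)), a)
  o1 <- rnorm(3); o2 <- rnorm(3)
  lhs <- rotational_acc_term(g, gd, o1 + o2)
  rhs <- rotational_acc_term(g, gd, o1) + rotational_acc_term(g, gd, o2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("corrected acceleration has constant gravity norm under steady spin", {
  # rigid body spinning at constant rate about an axis through the joint;
  # closed form: the joint centre feels only gravity
  n <- 200
  w <- 4
  o <- c(0.15, -0.05, 0.08)
  g <- matrix(rep(c(0, 0, w), each = n), n, 3)
  gd <- matrix(0, n, 3)
  grav <- t(sapply(seq_len(n), function(k) {
    th <- w * (k - 1) / 100
    c(cos(th) * 9.80665, sin(th) * 9.80665, 0)
  }))
  a <- grav + rotational_acc_term(g, gd, o)
  corr <- correct_acceleration(a, g, gd, o)
  expect_lt(max(abs(sqrt(rowSums(corr^2)) - 9.80665)), 1e-9)
})

test_that("flexion-positive convention produces a predominantly positive angle", {
  trial <- short_trial(seed = 3, duration_s = 10)
  fit <- kneeflex(trial$pair, reference = trial$reference,
                  control = kneeflex_control(filter_cutoff_hz = 150))
  expect_gt(mean(fit$angles$gyro$alpha), 0)
  # downstream angle equals truth regardless of the internal sign branch
  expect_lt(rms(fit$angles$fused$alpha - trial$truth$alpha_true), 1)
})

test_that("calibration serializes to JSON and back", {
  trial <- short_trial(seed = 3, duration_s = 10)
  fit <- kneeflex(trial$pair, reference = trial$reference,
                  control = kneeflex_control(filter_cutoff_hz = 150))
  path <- tempfile(fileext = ".json")
  write_calibration(fit$calibration, path)
  back <- read_calibration(path)
  expect_equal(back$j1, fit$calibration$j1, tolerance = 1e-12)
  expect_equal(back$o2, fit$calibration$o2, tolerance = 1e-12)
  expect_equal(back$alpha_offset, fit$calibration$alpha_offset,
               tolerance = 1e-12)
  # a reused calibration skips re-estimation but reproduces the fit
  fit2 <- kneeflex(trial$pair, reference = trial$reference,
                   calibration = back,
                   control = kneeflex_control(filter_cutoff_hz = 150))
  expect_equal(fit2$angles$fused$alpha, fit$angles$fused$alpha,
               tolerance = 1e-8)
})

test_that("axis estimation rejects degenerate windows", {
  z <- matrix(0, 50, 3)
  expect_error(estimate_joint_axes(z, z), "degenerate")
  expect_error(estimate_joint_axes(z[1:4, ], z[1:4, ]), "few")
})
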