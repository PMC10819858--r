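#' Default knee-flexion harmonic preset for running
#'
#' Harmonic decomposition of a running-style knee flexion curve over the
#' gait cycle: a small flexion wave during stance and a large swing-phase
#' peak. The default coefficients give a range of about 14-121 degrees with
#' roughly 19 degrees of flexion at foot strike, matching values reported
#' for treadmill running.
#'
#' @return A list with `c0` (mean, degrees) and `harmonics`, a matrix with
#'   columns `amp` (degrees) and `phase` (radians), one row per harmonic.
#' @export
knee_harmonics_running <- function() {
  list(c0 = 48.2575,
       harmonics = cbind(amp   = c(39.8122, 26.8988, 3.3829, 3.5098),
                         phase = c(2.1703, -1.8137, -0.3621, 3.0588)))
}

eval_harmonics <- function(tt, cycle_hz, c0, harmonics) {
  # returns alpha (deg) and first/second time derivatives (deg/s, deg/s^2)
  a <- rep(c0, length(tt)); ad <- numeric(length(tt)); add <- numeric(length(tt))
  if (!is.null(harmonics) && nrow(harmonics) > 0L) {
    for (k in seq_len(nrow(harmonics))) {
      w <- 2 * pi * k * cycle_hz
      ph <- w * tt + harmonics[k, "phase"]
      A <- harmonics[k, "amp"]
      a <- a + A * cos(ph)
      ad <- ad - A * w * sin(ph)
      add <- add - A * w^2 * cos(ph)
    }
  }
  list(a = a, ad = ad, add = add)
}

#' Simulate planar running-gait kinematics with a hinge knee
#'
#' Generates ground-truth sagittal-plane kinematics for a two-link
#' thigh-shank chain: the thigh orientation follows a periodic harmonic
#' series, the knee flexion angle alpha(t) is a truncated Fourier series
#' over the gait cycle, and the shank orientation is the thigh orientation
#' rotated by alpha about the (fixed, mediolateral) knee axis. The hip
#' translates with small vertical and fore-aft oscillations at step
#' frequency, emulating treadmill running at a given belt speed. All
#' derivatives are evaluated analytically, so simulated accelerations are
#' exact, not finite differences.
#'
#' Foot strikes are defined at integer gait-cycle phase (t = k / cycle_hz).
#'
#' @param speed_mps treadmill belt speed, m/s; scales the fore-aft hip
#'   oscillation amplitude.
#' @param cycle_hz per-leg gait cycle frequency, Hz.
#' @param duration_s duration, s; must exceed two cycles.
#' @param rate_hz sample rate, Hz.
#' @param angle_harmonics list as returned by [knee_harmonics_running()];
#'   the series must be non-negative everywhere (no hyperextension).
#' @param thigh_mean_deg,thigh_amp_deg,thigh_phase thigh orientation
#'   harmonic (degrees from vertical, positive forward).
#' @param hip_bounce_m,hip_sway_m vertical / fore-aft hip oscillation
#'   amplitudes, m (fore-aft additionally scaled by `speed_mps / 2.9`).
#' @param thigh_len_m hip-to-knee distance, m.
#' @param seed integer seed recorded in the output (the kinematics are
#'   deterministic; the seed is consumed by [simulate_imu()]).
#' @return A list of class `gait_kinematics` with per-sample time, knee
#'   angle (deg) and derivatives, segment orientations (rad) and
#'   derivatives, hip position/acceleration, and true strike times.
#' @export
simulate_gait_kinematics <- function(speed_mps = 2.9, cycle_hz = 1.4,
                                     duration_s = 60, rate_hz = 400,
                                     angle_harmonics = knee_harmonics_running(),
                                     thigh_mean_deg = 5, thigh_amp_deg = 30,
                                     thigh_phase = -2 * pi * 0.9,
                                     hip_bounce_m = 0.05, hip_sway_m = 0.02,
                                     thigh_len_m = 0.42,
                                     seed = 1L) {
  if (duration_s <= 0 || cycle_hz <= 0)
    stopf("duration_s and cycle_hz must be positive")
  if (duration_s <= 2 / cycle_hz)
    stopf("duration_s must exceed two gait cycles (%.2f s)", 2 / cycle_hz)
  n <- floor(duration_s * rate_hz) + 1L
  tt <- (seq_len(n) - 1L) / rate_hz

  al <- eval_harmonics(tt, cycle_hz, angle_harmonics$c0, angle_harmonics$harmonics)
  # hyperextension check on a dense grid over one cycle
  tg <- seq(0, 1 / cycle_hz, length.out = 2000L)
  if (min(eval_harmonics(tg, cycle_hz, angle_harmonics$c0,
                         angle_harmonics$harmonics)$a) < 0)
    stopf("angle harmonics produce negative knee flexion (hyperextension not modelled)")

  # thigh orientation about the mediolateral axis, rad (positive = forward)
  w <- 2 * pi * cycle_hz
  th_ph <- w * tt + thigh_phase
  th <- deg2rad(thigh_mean_deg + thigh_amp_deg * cos(th_ph))
  thd <- deg2rad(-thigh_amp_deg * w * sin(th_ph))
  thdd <- deg2rad(-thigh_amp_deg * w^2 * cos(th_ph))

  # shank = thigh rotated backward by alpha about the knee axis
  sh <- th - deg2rad(al$a)
  shd <- thd - deg2rad(al$ad)
  shdd <- thdd - deg2rad(al$add)

  # hip translation at step frequency (2 steps per per-leg cycle)
  ws <- 2 * w
  sway <- hip_sway_m * speed_mps / 2.9
  hip <- cbind(x = sway * cos(ws * tt + 0.5),
               y = 1.0 + hip_bounce_m * cos(ws * tt),
               z = 0)
  hip_acc <- cbind(x = -sway * ws^2 * cos(ws * tt + 0.5),
                   y = -hip_bounce_m * ws^2 * cos(ws * tt),
                   z = 0)

  strike_times <- seq(0, duration_s, by = 1 / cycle_hz)
  strike_times <- strike_times[strike_times <= tt[n] + 1e-12]

  structure(list(t = tt, rate_hz = rate_hz, cycle_hz = cycle_hz,
                 speed_mps = speed_mps,
                 alpha_deg = al$a, alpha_d = al$ad, alpha_dd = al$add,
                 theta_th = th, theta_th_d = thd, theta_th_dd = thdd,
                 theta_sh = sh, theta_sh_d = shd, theta_sh_dd = shdd,
                 hip = hip, hip_acc = hip_acc, thigh_len_m = thigh_len_m,
                 strike_times = strike_times, seed = as.integer(seed)),
            class = "gait_kinematics")
}

#' Sensor mounting specification
#'
#' Describes how a sensor sits on its segment: a segment-to-sensor rotation
#' (the mounting misalignment the calibration must absorb) and a lever arm
#' from the knee joint centre to the sensor origin, expressed in the
#' segment frame.
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1, tol 1e-9),
#'   mapping sensor-frame vectors to segment-frame vectors.
#' @param lever_arm 3-vector, m: sensor origin relative to the knee joint
#'   centre, segment frame.
#' @return Object of class `mounting_spec`.
#' @export
mounting_spec <- function(rotation = diag(3), lever_arm = c(0, -0.12, 0.02)) {
  if (!is_rotation_matrix(rotation))
    stopf("rotation must be orthonormal with determinant +1 (tol 1e-9)")
  stopifnot(length(lever_arm) == 3L, all(is.finite(lever_arm)))
  structure(list(rotation = rotation, lever_arm = as.numeric(lever_arm)),
            class = "mounting_spec")
}

#' Random mounting misalignment
#'
#' Draws a rotation about a uniformly random axis by an angle uniform on
#' `[0, max_angle_deg]`, composed with the segment-aligned pose. Uses the
#' current RNG state.
#'
#' @param max_angle_deg maximum misalignment angle, degrees.
#' @param lever_arm as in [mounting_spec()].
#' @return A `mounting_spec`.
#' @export
random_mounting <- function(max_angle_deg = 20, lever_arm = c(0, -0.12, 0.02)) {
  ax <- stats::rnorm(3L)
  ang <- deg2rad(stats::runif(1L, 0, max_angle_deg))
  mounting_spec(rot_axis_angle(ax, ang), lever_arm)
}

#' Sensor noise and impact-transient parameters
#'
#' @param gyro_sd gyroscope white-noise standard deviation, rad/s.
#' @param gyro_bias gyroscope bias magnitude per axis, rad/s. The shank
#'   sensor receives `+gyro_bias` and the thigh sensor `-gyro_bias` on each
#'   axis so the biases do not cancel in the joint angular-velocity
#'   difference.
#' @param accel_sd accelerometer white-noise standard deviation, m/s^2.
#' @param impact_amp foot-strike burst amplitude on the shank
#'   accelerometer, m/s^2.
#' @param impact_tau burst exponential decay time constant, s.
#' @param impact_freq burst oscillation frequency, Hz (a stand-in for
#'   soft-tissue ringing; see the package vignette).
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(gyro_sd = 0.02, gyro_bias = 0.005, accel_sd = 0.3,
                         impact_amp = 50, impact_tau = 0.03,
                         impact_freq = 25) {
  stopifnot(gyro_sd >= 0, accel_sd >= 0, impact_amp >= 0,
            impact_tau > 0, impact_freq > 0)
  structure(list(gyro_sd = gyro_sd, gyro_bias = gyro_bias,
                 accel_sd = accel_sd, impact_amp = impact_amp,
                 impact_tau = impact_tau, impact_freq = impact_freq),
            class = "noise_params")
}

#' Noise-free preset (impacts optional)
#' @param impacts if `TRUE`, keep the foot-strike bursts (default drops
#'   sensor noise and bias only).
#' @rdname noise_params
#' @export
noise_free <- function(impacts = TRUE) {
  noise_params(gyro_sd = 0, gyro_bias = 0, accel_sd = 0,
               impact_amp = if (impacts) 50 else 0)
}

# second time-derivative of Rz(theta) %*% r for a segment-frame vector r:
# Rz(theta) (thdd * z x r + thd^2 * z x (z x r)), vectorised over samples
planar_point_acc <- function(theta, thd, thdd, r) {
  zxr <- c(-r[2L], r[1L], 0)
  zzr <- c(-r[1L], -r[2L], 0)
  bx <- thdd * zxr[1L] + thd^2 * zzr[1L]
  by <- thdd * zxr[2L] + thd^2 * zzr[2L]
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * bx - st * by, st * bx + ct * by, 0)
}

# rows of Rz(theta)^T %*% W
rotz_t_rows <- function(theta, W) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * W[, 1L] + st * W[, 2L],
        -st * W[, 1L] + ct * W[, 2L],
        W[, 3L])
}

#' Simulate dual-IMU signals from gait kinematics
#'
#' Produces the shank and thigh sensor streams implied by a
#' [simulate_gait_kinematics()] trajectory and a mounting specification,
#' plus the ground truth needed to score every downstream estimate. The
#' gyroscope is the segment angular velocity mapped through the mounting
#' rotation plus bias and white noise; the accelerometer is the exact
#' specific force at the sensor position (joint-centre acceleration plus
#' lever-arm rotational terms minus gravity, in the sensor frame) plus
#' white noise; a decaying oscillatory burst is added to the shank
#' accelerometer at each foot strike.
#'
#' @param kin a `gait_kinematics` object.
#' @param mounting list with elements `shank` and `thigh`, each a
#'   [mounting_spec()].
#' @param noise a [noise_params()] object.
#' @param seed integer seed for the measurement noise.
#' @return A list with `pair` (a [sensor_pair()]) and `truth`, a
#'   `synthetic_ground_truth` list holding `alpha_true` (deg),
#'   `j1_true`, `j2_true` (unit axes, sensor frames), `o1_true`, `o2_true`
#'   (joint centre, m, sensor frames), `strike_indices_true`, the noise
#'   parameters, mounting, and seed.
#' @export
simulate_imu <- function(kin, mounting, noise = noise_params(), seed = 1L) {
  stopifnot(inherits(kin, "gait_kinematics"),
            inherits(mounting$shank, "mounting_spec"),
            inherits(mounting$thigh, "mounting_spec"),
            inherits(noise, "noise_params"))
  set.seed(as.integer(seed))
  n <- length(kin$t)
  zhat <- c(0, 0, 1)
  g_world <- c(0, -GRAVITY, 0)
  m1 <- mounting$shank$rotation; r1 <- mounting$shank$lever_arm
  m2 <- mounting$thigh$rotation; r2 <- mounting$thigh$lever_arm

  j1 <- drop(crossprod(m1, zhat)); j2 <- drop(crossprod(m2, zhat))
  # lever vector consistent with the subtractive correction a - Gamma(o):
  # from the joint centre to the sensor, expressed in the sensor frame
  o1 <- drop(crossprod(m1, r1)); o2 <- drop(crossprod(m2, r2))

  # gyros: segment rate about the world z axis, expressed in sensor frames
  gyr1 <- outer(kin$theta_sh_d, j1)
  gyr2 <- outer(kin$theta_th_d, j2)

  # knee joint-centre acceleration (world frame)
  d_th <- c(0, -kin$thigh_len_m, 0)  # hip-to-knee in the thigh frame
  knee_acc <- kin$hip_acc +
    planar_point_acc(kin$theta_th, kin$theta_th_d, kin$theta_th_dd, d_th)

  # specific force at the sensors, world frame
  w1 <- knee_acc +
    planar_point_acc(kin$theta_sh, kin$theta_sh_d, kin$theta_sh_dd, r1)
  w2 <- knee_acc +
    planar_point_acc(kin$theta_th, kin$theta_th_d, kin$theta_th_dd, r2)
  w1 <- sweep(w1, 2L, g_world)
  w2 <- sweep(w2, 2L, g_world)

  # world -> sensor: m_i^T Rz(theta_i)^T
  acc1 <- rotz_t_rows(kin$theta_sh, w1) %*% m1
  acc2 <- rotz_t_rows(kin$theta_th, w2) %*% m2

  strike_idx <- pmin(round(kin$strike_times * kin$rate_hz) + 1L, n)
  strike_idx <- sort(unique(strike_idx))

  # foot-strike burst on the shank accelerometer (sensor frame); the shock
  # adds along the instantaneous specific-force direction so the measured
  # norm spikes at contact, as on real tibial-shock traces
  if (noise$impact_amp > 0) {
    span <- ceiling(8 * noise$impact_tau * kin$rate_hz)
    for (s in strike_idx) {
      dir1 <- acc1[s, ]
      nd <- vnorm(dir1)
      dir1 <- if (nd > 1e-6) dir1 / nd else c(0, 1, 0)
      idx <- s:min(n, s + span)
      dt <- (idx - s) / kin$rate_hz
      burst <- noise$impact_amp * exp(-dt / noise$impact_tau) *
        cos(2 * pi * noise$impact_freq * dt)
      acc1[idx, ] <- acc1[idx, ] + outer(burst, dir1)
    }
  }

  if (noise$gyro_bias != 0) {
    gyr1 <- gyr1 + noise$gyro_bias
    gyr2 <- gyr2 - noise$gyro_bias
  }
  if (noise$gyro_sd > 0) {
    gyr1 <- gyr1 + matrix(stats::rnorm(3L * n, sd = noise$gyro_sd), n, 3L)
    gyr2 <- gyr2 + matrix(stats::rnorm(3L * n, sd = noise$gyro_sd), n, 3L)
  }
  if (noise$accel_sd > 0) {
    acc1 <- acc1 + matrix(stats::rnorm(3L * n, sd = noise$accel_sd), n, 3L)
    acc2 <- acc2 + matrix(stats::rnorm(3L * n, sd = noise$accel_sd), n, 3L)
  }

  pair <- sensor_pair(
    imu_recording(kin$t, acc1, gyr1, kin$rate_hz, sensor_id = 1L),
    imu_recording(kin$t, acc2, gyr2, kin$rate_hz, sensor_id = 2L))
  truth <- structure(list(alpha_true = kin$alpha_deg,
                          j1_true = j1, j2_true = j2,
                          o1_true = o1, o2_true = o2,
                          strike_indices_true = strike_idx,
                          noise = noise, mounting = mounting,
                          kin = kin, seed = as.integer(seed)),
                     class = "synthetic_ground_truth")
  list(pair = pair, truth = truth)
}

#' One-call synthetic running trial
#'
#' Convenience wrapper: draws a random mounting misalignment for each
#' sensor, simulates the kinematics and the IMU pair, and returns the pair
#' together with the ground truth and a reference angle series. All
#' randomness flows from `seed`.
#'
#' @param duration_s,rate_hz,cycle_hz,speed_mps passed to
#'   [simulate_gait_kinematics()].
#' @param noise a [noise_params()] object.
#' @param max_misalign_deg maximum random mounting misalignment, degrees.
#' @param mounting optional explicit mounting list (overrides the random
#'   draw).
#' @param seed integer seed.
#' @param ... further arguments to [simulate_gait_kinematics()].
#' @return list with `pair`, `truth`, and `reference` (an
#'   [angle_series()] of the true knee angle).
#' @export
simulate_running_trial <- function(duration_s = 60, rate_hz = 400,
                                   cycle_hz = 1.4, speed_mps = 2.9,
                                   noise = noise_params(),
                                   max_misalign_deg = 20,
                                   mounting = NULL, seed = 1L, ...) {
  set.seed(as.integer(seed))
  if (is.null(mounting)) {
    mounting <- list(
      shank = random_mounting(max_misalign_deg, lever_arm = c(0.03, -0.12, 0.02)),
      thigh = random_mounting(max_misalign_deg, lever_arm = c(0.04, 0.15, 0.03)))
  }
  kin <- simulate_gait_kinematics(speed_mps = speed_mps, cycle_hz = cycle_hz,
                                  duration_s = duration_s, rate_hz = rate_hz,
                                  seed = seed, ...)
  sim <- simulate_imu(kin, mounting, noise,
                      seed = (as.integer(seed) * 7919L + 13L) %% 2147483647L)
  sim$reference <- angle_series(kin$t, kin$alpha_deg, source = "truth")
  sim
}
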