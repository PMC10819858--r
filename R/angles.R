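# cumulative trapezoidal integral of a scalar series sampled at dt
cumtrapz_scalar <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-n] + x[-1L]) / 2 * dt))
}

#' Project angular velocity onto the knee axis
#'
#' Per-sample dot product \eqn{\tilde g_i(t) = g_i(t) \cdot j_i}: the
#' component of each sensor's angular velocity about the knee axis, rad/s.
#'
#' @param g n x 3 angular velocity, rad/s.
#' @param j unit axis 3-vector.
#' @return Numeric vector, rad/s.
#' @export
project_gyro <- function(g, j) {
  if (abs(vnorm(j) - 1) > 1e-6) stopf("j must be a unit vector")
  drop(as.matrix(g) %*% j)
}

#' Gyroscope-integrated knee angle
#'
#' Integrates the difference of the axis-projected angular rates
#' (trapezoidal rule) from an initial angle:
#' \deqn{\alpha_{gyr}(t) = \alpha_0 + \int_0^t (\tilde g_1 - \tilde g_2)\,d\tau.}
#' Drift-free short term but accumulates gyroscope bias linearly in time.
#'
#' @param g1t,g2t axis-projected rates, rad/s ([project_gyro()]).
#' @param dt sample interval, s.
#' @param alpha0 initial knee angle, degrees.
#' @return An [angle_series()] with `source = "gyro"`.
#' @export
gyro_angle <- function(g1t, g2t, dt, alpha0 = 0) {
  if (length(g1t) != length(g2t)) stopf("g1t and g2t lengths differ")
  alpha <- alpha0 + rad2deg(cumtrapz_scalar(g1t - g2t, dt))
  angle_series(t = (seq_along(g1t) - 1L) * dt, alpha = alpha, source = "gyro")
}

#' Signed angle between two 2-D vectors
#'
#' Counterclockwise angle from `u` to `v` in degrees, in (-180, 180].
#' Either vector with norm below `eps` makes the result `NA` (degenerate
#' projection).
#'
#' @param u,v length-2 numeric vectors, or n x 2 matrices for vectorised
#'   use.
#' @param eps degeneracy threshold on each vector's norm.
#' @return Degrees (scalar or vector), `NA` where degenerate.
#' @export
signed_angle_2d <- function(u, v, eps = 0.05) {
  U <- if (is.null(dim(u))) matrix(u, ncol = 2L) else as.matrix(u)
  V <- if (is.null(dim(v))) matrix(v, ncol = 2L) else as.matrix(v)
  cross <- U[, 1L] * V[, 2L] - U[, 2L] * V[, 1L]
  dot <- U[, 1L] * V[, 1L] + U[, 2L] * V[, 2L]
  ang <- rad2deg(atan2(cross, dot))
  ang[ang <= -180] <- 180
  bad <- sqrt(rowSums(U^2)) < eps | sqrt(rowSums(V^2)) < eps
  ang[bad] <- NA_real_
  if (length(ang) == 1L) ang[1L] else ang
}

#' Accelerometer-derived knee angle
#'
#' Projects both lever-arm-corrected accelerations into the joint plane
#' (bases `x_i, y_i` from the calibration) and takes the signed 2-D angle
#' between them, plus the calibration's constant offset. Samples where
#' either projected vector is shorter than `eps` are flagged invalid and
#' excluded from filter updates downstream.
#'
#' @param a1c,a2c n x 3 corrected accelerations ([correct_acceleration()]),
#'   m/s^2.
#' @param calib a `joint_calibration`.
#' @param t optional time vector (defaults to sample index).
#' @param eps degeneracy threshold on the projected magnitude, m/s^2.
#' @return An [angle_series()] with `source = "accel"`; the 2-D
#'   projections are attached as attributes `proj1` and `proj2` for the
#'   extended Kalman filter.
#' @export
accel_angle <- function(a1c, a2c, calib, t = NULL, eps = 0.05) {
  a1c <- as.matrix(a1c); a2c <- as.matrix(a2c)
  u <- cbind(a1c %*% calib$x1, a1c %*% calib$y1)
  v <- cbind(a2c %*% calib$x2, a2c %*% calib$y2)
  raw <- signed_angle_2d(u, v, eps = eps)
  if (!is.null(calib$alpha_ref_raw)) {
    # express each sample relative to the calibration's reference raw angle
    # so a knee range of up to 360 deg never hits the atan2 branch cut
    ang <- calib$alpha_ref_raw + wrap_pm180(raw - calib$alpha_ref_raw) +
      calib$alpha_offset
  } else {
    ang <- raw + calib$alpha_offset
  }
  valid <- !is.na(ang)
  ang[!valid] <- 0  # placeholder; excluded via `valid`
  if (is.null(t)) t <- seq_len(nrow(a1c)) - 1L
  out <- angle_series(t = t, alpha = ang, source = "accel", valid = valid)
  attr(out, "proj1") <- u
  attr(out, "proj2") <- v
  out
}
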