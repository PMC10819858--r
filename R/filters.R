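#' Fusion filter configuration
#'
#' The three fusion variants share a scalar state, the knee flexion angle
#' in degrees, predicted each step from the axis-projected gyroscope
#' difference (\eqn{x_k = x_{k-1} + \Delta t\, u_{k-1}}). They differ in
#' the measurement model: the KF observes the accelerometer-derived angle
#' directly, the EKF observes the thigh's projected acceleration as a
#' rotation of the shank's by the state, and the CF is a fixed-gain blend.
#'
#' @param kind `"kf"`, `"ekf"` or `"cf"`.
#' @param q process-noise variance (deg^2 per sample); uncertainty of the
#'   gyroscope prediction.
#' @param r_kf KF measurement-noise variance (deg^2); conventionally fixed
#'   at 1 while `q` is tuned.
#' @param r_ekf length-2 diagonal of the EKF measurement covariance, in
#'   (m/s^2)^2, for the in-plane x and y acceleration components.
#' @param lam CF gain in `[0, 1]`; 1 trusts the accelerometer angle fully,
#'   0 reduces to pure gyroscope integration.
#' @param alpha0 initial angle, degrees.
#' @param p0 initial state variance, deg^2.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(kind = c("cf", "kf", "ekf"), q = 1e-3, r_kf = 1,
                          r_ekf = c(1, 1), lam = 0.01, alpha0 = 0, p0 = 1) {
  kind <- match.arg(kind)
  stopifnot(q >= 0, r_kf > 0, all(r_ekf > 0), lam >= 0, lam <= 1, p0 >= 0)
  structure(list(kind = kind, q = q, r_kf = r_kf, r_ekf = r_ekf,
                 lam = lam, alpha0 = alpha0, p0 = p0),
            class = "filter_config")
}

new_filter_trace <- function(alpha, p, updated, kind, dt) {
  structure(list(alpha_hat = alpha, p = p, updated = updated,
                 kind = kind, dt = dt),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf("<filter_trace> %s, %d samples, %.1f%% updated\n",
              toupper(x$kind), length(x$alpha_hat), 100 * mean(x$updated)))
  invisible(x)
}

#' Linear Kalman filter for the knee angle
#'
#' Scalar-state KF: prediction \eqn{\hat x_{k|k-1} = \hat x_{k-1} +
#' \Delta t\,u_{k-1}}, \eqn{P_{k|k-1} = P_{k-1} + Q}; where the gate is
#' open and the measurement valid, gain \eqn{K = P/(P+R)} and update
#' against the accelerometer angle. Gated or invalid samples carry the
#' prediction only (gyroscope dead reckoning through foot-strike impacts).
#'
#' @param u gyroscope-difference input \eqn{\tilde g_1 - \tilde g_2},
#'   rad/s (converted to deg/s internally).
#' @param z accelerometer angle measurements, degrees ([accel_angle()]).
#' @param gate logical per sample: `TRUE` allows the measurement update.
#' @param dt sample interval, s.
#' @param cfg a [filter_config()] with `kind = "kf"`.
#' @param z_valid logical per sample; invalid measurements are skipped.
#' @return A `filter_trace` with `alpha_hat` (deg), `p` (deg^2) and
#'   `updated`.
#' @export
run_kf <- function(u, z, gate, dt, cfg, z_valid = NULL) {
  stopifnot(inherits(cfg, "filter_config"), cfg$kind == "kf")
  n <- length(z)
  if (length(u) != n || length(gate) != n) stopf("series lengths differ")
  if (is.null(z_valid)) z_valid <- rep(TRUE, n)
  u_deg <- rad2deg(u)
  xh <- numeric(n); pv <- numeric(n); upd <- logical(n)
  x <- cfg$alpha0; p <- cfg$p0
  xh[1L] <- x; pv[1L] <- p
  for (k in 2:n) {
    # trapezoidal gyro increment: agrees exactly with gyro_angle() when no
    # update ever fires
    x <- x + dt * (u_deg[k - 1L] + u_deg[k]) / 2
    p <- p + cfg$q
    if (gate[k] && z_valid[k]) {
      K <- p / (p + cfg$r_kf)
      x <- x + K * (z[k] - x)
      p <- (1 - K) * p
      upd[k] <- TRUE
    }
    xh[k] <- x; pv[k] <- p
  }
  new_filter_trace(xh, pv, upd, "kf", dt)
}

# EKF observation model: thigh projection as rotation of shank projection
# by the state (degrees). Returns h (2-vector) and Jacobian H (2x1, per
# degree of state).
ekf_h <- function(x_deg, u1) {
  xr <- deg2rad(x_deg)
  cx <- cos(xr); sx <- sin(xr)
  h <- c(cx * u1[1L] - sx * u1[2L], sx * u1[1L] + cx * u1[2L])
  H <- (pi / 180) * c(-sx * u1[1L] - cx * u1[2L], cx * u1[1L] - sx * u1[2L])
  list(h = h, H = H)
}

#' Extended Kalman filter for the knee angle
#'
#' Same scalar prediction as [run_kf()]; the measurement is the thigh's
#' in-plane projected acceleration, modelled as the shank's projection
#' rotated by the state:
#' \deqn{h(x) = R(x)\,(\tilde a_1 \cdot x_1, \tilde a_1 \cdot y_1)^T,}
#' with the 2x2 innovation covariance inverted in closed form. Gated or
#' invalid samples carry the prediction.
#'
#' @param u gyroscope-difference input, rad/s.
#' @param a1_proj,a2_proj n x 2 in-plane projections of the corrected
#'   shank / thigh accelerations (attributes of [accel_angle()]).
#' @param gate,dt,cfg,z_valid as in [run_kf()] (`kind = "ekf"`).
#' @return A `filter_trace`.
#' @export
run_ekf <- function(u, a1_proj, a2_proj, gate, dt, cfg, z_valid = NULL) {
  stopifnot(inherits(cfg, "filter_config"), cfg$kind == "ekf")
  n <- nrow(a2_proj)
  if (length(u) != n || length(gate) != n || nrow(a1_proj) != n)
    stopf("series lengths differ")
  if (is.null(z_valid)) z_valid <- rep(TRUE, n)
  u_deg <- rad2deg(u)
  r <- cfg$r_ekf
  xh <- numeric(n); pv <- numeric(n); upd <- logical(n)
  x <- cfg$alpha0; p <- cfg$p0
  xh[1L] <- x; pv[1L] <- p
  for (k in 2:n) {
    x <- x + dt * (u_deg[k - 1L] + u_deg[k]) / 2
    p <- p + cfg$q
    if (gate[k] && z_valid[k]) {
      hh <- ekf_h(x, a1_proj[k, ])
      H <- hh$H
      # S = H p H^T + R (2x2, diagonal R)
      s11 <- p * H[1L]^2 + r[1L]
      s22 <- p * H[2L]^2 + r[2L]
      s12 <- p * H[1L] * H[2L]
      det_s <- s11 * s22 - s12^2
      if (!is.finite(det_s) || det_s <= 0)
        stopf("singular innovation covariance at sample %d (r_ekf too small?)", k)
      # K = p H^T S^-1 (1x2)
      K1 <- p * (H[1L] * s22 - H[2L] * s12) / det_s
      K2 <- p * (H[2L] * s11 - H[1L] * s12) / det_s
      innov <- a2_proj[k, ] - hh$h
      x <- x + K1 * innov[1L] + K2 * innov[2L]
      p <- (1 - (K1 * H[1L] + K2 * H[2L])) * p
      upd[k] <- TRUE
    }
    xh[k] <- x; pv[k] <- p
  }
  new_filter_trace(xh, pv, upd, "ekf", dt)
}

#' Complementary filter for the knee angle
#'
#' Fixed-gain recursion blending the drift-free accelerometer angle with
#' the smooth gyroscope increments:
#' \deqn{\alpha_k = \lambda\,\alpha_{acc,k} + (1-\lambda)
#'   (\alpha_{k-1} + \alpha_{gyr,k} - \alpha_{gyr,k-1}).}
#' On gated or invalid samples the gain is treated as zero for that step
#' (pure gyroscope increment).
#'
#' @param alpha_acc accelerometer angle, degrees.
#' @param alpha_gyr gyroscope-integrated angle, degrees.
#' @param gate,dt,cfg,z_valid as in [run_kf()] (`kind = "cf"`).
#' @return A `filter_trace` (`p` is `NA`; the CF tracks no covariance).
#' @export
run_cf <- function(alpha_acc, alpha_gyr, gate, dt, cfg, z_valid = NULL) {
  stopifnot(inherits(cfg, "filter_config"), cfg$kind == "cf")
  n <- length(alpha_acc)
  if (length(alpha_gyr) != n || length(gate) != n) stopf("series lengths differ")
  if (is.null(z_valid)) z_valid <- rep(TRUE, n)
  xh <- numeric(n); upd <- logical(n)
  x <- cfg$alpha0
  xh[1L] <- x
  for (k in 2:n) {
    lam <- if (gate[k] && z_valid[k]) cfg$lam else 0
    upd[k] <- lam > 0
    x <- lam * alpha_acc[k] + (1 - lam) * (x + alpha_gyr[k] - alpha_gyr[k - 1L])
    xh[k] <- x
  }
  new_filter_trace(xh, rep(NA_real_, n), upd, "cf", dt)
}
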