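#' Construct an IMU recording
#'
#' Container for one sensor's synchronized triaxial accelerometer and
#' gyroscope streams on a uniform timeline. Internal units are SI
#' throughout the package: m/s^2 for specific force and rad/s for angular
#' velocity; conversion from g-units or deg/s happens at the I/O boundary
#' (see [read_imu_csv()]).
#'
#' @param t numeric vector of sample times in seconds, uniformly spaced.
#' @param acc n x 3 numeric matrix of specific force, m/s^2.
#' @param gyr n x 3 numeric matrix of angular velocity, rad/s.
#' @param rate_hz sampling rate in Hz; must match `diff(t)` to within 1e-6 s.
#' @param sensor_id 1 for the shank sensor, 2 for the thigh sensor.
#' @return An object of class `imu_recording`: a list with fields
#'   `t`, `acc`, `gyr`, `rate_hz`, `sensor_id`, `n`.
#' @export
imu_recording <- function(t, acc, gyr, rate_hz, sensor_id = 1L) {
  t <- as.numeric(t)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(t)
  if (ncol(acc) != 3L || ncol(gyr) != 3L)
    stopf("acc and gyr must have 3 columns")
  if (nrow(acc) != n || nrow(gyr) != n)
    stopf("t, acc and gyr must have equal length (got %d, %d, %d)",
          n, nrow(acc), nrow(gyr))
  if (!all(is.finite(t)) || !all(is.finite(acc)) || !all(is.finite(gyr)))
    stopf("all samples must be finite")
  if (n >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0)) stopf("t must be strictly increasing")
    dev <- max(abs(dt - 1 / rate_hz))
    if (dev > 1e-6)
      stopf("non-uniform timeline: diff(t) deviates from 1/rate_hz by %.3g s",
            dev)
  }
  if (!sensor_id %in% c(1L, 2L)) stopf("sensor_id must be 1 (shank) or 2 (thigh)")
  structure(list(t = t, acc = unname(acc), gyr = unname(gyr),
                 rate_hz = rate_hz, sensor_id = as.integer(sensor_id), n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> sensor %d (%s), %d samples @ %g Hz (%.2f s)\n",
              x$sensor_id, if (x$sensor_id == 1L) "shank" else "thigh",
              x$n, x$rate_hz, x$n / x$rate_hz))
  cat(sprintf("  |acc| in [%.2f, %.2f] m/s^2; |gyr| in [%.3f, %.3f] rad/s\n",
              min(row_norms(x$acc)), max(row_norms(x$acc)),
              min(row_norms(x$gyr)), max(row_norms(x$gyr))))
  invisible(x)
}

#' @export
as.data.frame.imu_recording <- function(x, ...) {
  data.frame(time_s = x$t,
             ax = x$acc[, 1L], ay = x$acc[, 2L], az = x$acc[, 3L],
             gx = x$gyr[, 1L], gy = x$gyr[, 2L], gz = x$gyr[, 3L])
}

#' Pair the shank and thigh recordings
#'
#' Both recordings must share the sampling rate and sample count; callers
#' resample or truncate to a common timeline first.
#'
#' @param shank,thigh `imu_recording` objects (sensor 1 and 2).
#' @return An object of class `sensor_pair`.
#' @export
sensor_pair <- function(shank, thigh) {
  stopifnot(inherits(shank, "imu_recording"), inherits(thigh, "imu_recording"))
  if (shank$rate_hz != thigh$rate_hz)
    stopf("shank and thigh rates differ (%g vs %g Hz)",
          shank$rate_hz, thigh$rate_hz)
  if (shank$n != thigh$n)
    stopf("shank and thigh sample counts differ (%d vs %d)", shank$n, thigh$n)
  structure(list(shank = shank, thigh = thigh,
                 rate_hz = shank$rate_hz, n = shank$n, t = shank$t),
            class = "sensor_pair")
}

#' @export
print.sensor_pair <- function(x, ...) {
  cat(sprintf("<sensor_pair> %d samples @ %g Hz (%.2f s)\n",
              x$n, x$rate_hz, x$n / x$rate_hz))
  invisible(x)
}

#' Time-stamped knee-angle series
#'
#' @param t time vector, seconds.
#' @param alpha knee flexion angle, degrees.
#' @param source one of `"gyro"`, `"accel"`, `"kf"`, `"ekf"`, `"cf"`,
#'   `"reference"`, `"truth"`.
#' @param valid logical per sample; `FALSE` marks samples where the
#'   accelerometer projection was degenerate.
#' @return Object of class `angle_series`.
#' @export
angle_series <- function(t, alpha, source, valid = NULL) {
  source <- match.arg(source,
                      c("gyro", "accel", "kf", "ekf", "cf", "reference", "truth"))
  if (length(t) != length(alpha)) stopf("t and alpha lengths differ")
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  if (any(!is.finite(alpha[valid]))) stopf("alpha must be finite where valid")
  structure(list(t = as.numeric(t), alpha = as.numeric(alpha),
                 source = source, valid = as.logical(valid)),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<angle_series> source=%s, %d samples (%d valid), range [%.1f, %.1f] deg\n",
              x$source, length(x$t), sum(ok),
              min(x$alpha[ok]), max(x$alpha[ok])))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(time_s = x$t, alpha_deg = x$alpha, source = x$source,
             valid = x$valid)
}
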