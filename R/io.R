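#' Read an IMU recording from CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a mandatory
#' header row naming the columns `time_s, ax, ay, az, gx, gy, gz`.
#' Acceleration may be in m/s^2 or g, angular velocity in rad/s or deg/s;
#' both are converted to SI on read. Values outside +/-16 g or
#' +/-2000 deg/s (typical sport-IMU ranges) trigger a warning.
#'
#' @param path CSV file path.
#' @param acc_units `"m_s2"` or `"g"`.
#' @param gyro_units `"rad_s"` or `"deg_s"`.
#' @param rate_hz optional sample rate; inferred from the median time step
#'   when omitted.
#' @param sensor_id 1 (shank) or 2 (thigh).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, acc_units = c("m_s2", "g"),
                         gyro_units = c("rad_s", "deg_s"),
                         rate_hz = NULL, sensor_id = 1L) {
  acc_units <- match.arg(acc_units)
  gyro_units <- match.arg(gyro_units)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stopf("empty file: %s", path)
  for (col in need) {
    if (!is.numeric(df[[col]]))
      stopf("non-numeric values in column %s", col)
  }
  tt <- df$time_s
  if (is.null(rate_hz)) {
    if (length(tt) < 2L) stopf("cannot infer sample rate from one row")
    rate_hz <- 1 / stats::median(diff(tt))
  }
  dtv <- diff(tt)
  bad <- which(abs(dtv - 1 / rate_hz) > 1e-6)
  if (length(bad))
    stopf("non-uniform or non-monotonic time at row %d (dt = %.6g s)",
          bad[1L] + 1L, dtv[bad[1L]])
  acc <- as.matrix(df[, c("ax", "ay", "az")])
  gyr <- as.matrix(df[, c("gx", "gy", "gz")])
  if (acc_units == "g") acc <- acc * GRAVITY
  if (gyro_units == "deg_s") gyr <- deg2rad(gyr)
  if (max(row_norms(acc)) > 16 * GRAVITY)
    warnf("acceleration exceeds 16 g: check units")
  if (max(abs(gyr)) > deg2rad(2000))
    warnf("angular velocity exceeds 2000 deg/s: check units")
  imu_recording(tt, acc, gyr, rate_hz, sensor_id = sensor_id)
}

#' Write an IMU recording to CSV
#' @param rec an [imu_recording()]; written in SI units with 6
#'   significant digits.
#' @param path output path.
#' @export
write_imu_csv <- function(rec, path) {
  df <- as.data.frame(rec)
  df[] <- lapply(df, function(v) signif(v, 6L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference knee-angle series from CSV
#'
#' Columns `time_s, alpha_deg` (e.g. exported motion-capture angles).
#'
#' @param path CSV path.
#' @return An [angle_series()] with `source = "reference"`.
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "alpha_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stopf("empty file: %s", path)
  for (col in need)
    if (!is.numeric(df[[col]])) stopf("non-numeric values in column %s", col)
  if (any(diff(df$time_s) <= 0)) stopf("time_s must be strictly increasing")
  angle_series(df$time_s, df$alpha_deg, source = "reference")
}

#' Write an angle series to CSV
#' @param series an [angle_series()].
#' @param path output path.
#' @export
write_angle_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$time_s <- signif(df$time_s, 6L)
  df$alpha_deg <- signif(df$alpha_deg, 6L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# flat config keys accepted in YAML pipeline configs, mapped onto
# kneeflex_control() arguments
config_key_map <- c(
  "peaks.min_cycle_s" = "peaks_min_cycle_s",
  "peaks.min_prominence_g" = "peaks_min_prominence_g",
  "window.lo_pct" = "window_lo_pct",
  "window.hi_pct" = "window_hi_pct",
  "gate.halfwidth_pct" = "gate_halfwidth_pct",
  "filter.cutoff_hz" = "filter_cutoff_hz",
  "filter.order" = "filter_order",
  "filter.q" = "q",
  "filter.r" = "r_kf",
  "filter.lambda" = "lam",
  "filter.p0" = "p0",
  "calib.restarts" = "restarts",
  "calib.max_opt_samples" = "max_opt_samples",
  "accel.eps" = "eps",
  "seed" = "seed")

#' Read a pipeline configuration from YAML
#'
#' Flat-key YAML document; recognised keys are the
#' [kneeflex_control()] parameters (dotted, e.g. `filter.lambda`), plus
#' `filter.kind`, `filter.r2` (EKF diagonal), `filter.alpha0_deg`,
#' `io.gyro_units`, `io.acc_units` and `io.rate_hz`. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return List with `control` (a `kneeflex_control`), `filter`,
#'   `alpha0`, and `io` (units and rate).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  extra <- c("filter.kind", "filter.r2", "filter.alpha0_deg",
             "io.gyro_units", "io.acc_units", "io.rate_hz", "log.level")
  unknown <- setdiff(names(y), c(names(config_key_map), extra))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  args <- list()
  for (k in intersect(names(y), names(config_key_map)))
    args[[config_key_map[[k]]]] <- y[[k]]
  if (!is.null(y[["filter.r2"]])) args$r_ekf <- as.numeric(y[["filter.r2"]])
  control <- do.call(kneeflex_control, args)
  list(control = control,
       filter = if (is.null(y[["filter.kind"]])) "cf" else y[["filter.kind"]],
       alpha0 = y[["filter.alpha0_deg"]],
       io = list(gyro_units = y[["io.gyro_units"]] %||% "rad_s",
                 acc_units = y[["io.acc_units"]] %||% "m_s2",
                 rate_hz = y[["io.rate_hz"]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write synthetic ground truth as a JSON sidecar
#' @param truth a `synthetic_ground_truth` (from [simulate_imu()]).
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(j1_true = truth$j1_true, j2_true = truth$j2_true,
              o1_true = truth$o1_true, o2_true = truth$o2_true,
              strike_indices_true = truth$strike_indices_true,
              alpha_range_deg = range(truth$alpha_true),
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
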