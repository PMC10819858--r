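#' Control parameters for a kneeflex fit
#'
#' Collects every tunable of the processing chain with its default. All
#' defaults mirror the running-gait pipeline the package implements: peak
#' detection on the unfiltered shank acceleration norm, a 40-80% mid-cycle
#' optimization window, a 5% update gate around each strike, and 4th-order
#' zero-phase 7 Hz Butterworth filtering.
#'
#' @param peaks_min_cycle_s minimum strike spacing, s.
#' @param peaks_min_prominence_g minimum peak prominence, g.
#' @param window_lo_pct,window_hi_pct optimization window, percent of
#'   cycle.
#' @param gate_halfwidth_pct update-gate half width, percent of cycle.
#' @param filter_cutoff_hz,filter_order zero-phase Butterworth design.
#' @param restarts random restarts for both calibration optimizations.
#' @param max_opt_samples cap on optimization window samples (uniform
#'   subsampling beyond it).
#' @param q,r_kf,r_ekf,lam,p0 fusion-filter parameters
#'   ([filter_config()]).
#' @param eps degeneracy threshold for the accelerometer projection,
#'   m/s^2.
#' @param seed integer seed for the calibration restarts.
#' @return A list of class `kneeflex_control`.
#' @export
kneeflex_control <- function(peaks_min_cycle_s = 0.4,
                             peaks_min_prominence_g = 4,
                             window_lo_pct = 40, window_hi_pct = 80,
                             gate_halfwidth_pct = 5,
                             filter_cutoff_hz = 7, filter_order = 4,
                             restarts = 10L, max_opt_samples = 20000L,
                             q = 1e-3, r_kf = 1, r_ekf = c(1, 1),
                             lam = 0.01, p0 = 1, eps = 0.05,
                             seed = 1L) {
  structure(as.list(environment()), class = "kneeflex_control")
}

#' Fit the knee flexion angle from a shank-thigh IMU pair
#'
#' The full dynamic-calibration estimator. In order: foot strikes are
#' detected on the unfiltered shank acceleration norm; gait-cycle phase,
#' the 40-80% optimization window, and the impact update-gate are built;
#' the knee-axis directions are identified from the unfiltered windowed
#' gyroscopes; all signals are zero-phase low-pass filtered (7 Hz) and
#' differentiated; the joint-centre positions are identified from the
#' filtered windowed data; accelerations are lever-arm corrected; the
#' gyroscope-integrated and accelerometer-derived knee angles are formed;
#' and the chosen fusion filter (CF, KF or EKF) blends them, gating
#' measurement updates around each strike. No magnetometers, static poses
#' or anthropometrics are involved.
#'
#' @param pair a [sensor_pair()] (shank = sensor 1, thigh = sensor 2).
#' @param reference optional reference [angle_series()] (e.g. motion
#'   capture); used for the initial angle, the accelerometer angle offset,
#'   and accuracy metrics.
#' @param filter fusion filter kind: `"cf"` (default, recommended),
#'   `"kf"`, or `"ekf"`.
#' @param control a [kneeflex_control()] list.
#' @param strikes optional known foot-strike sample indices, overriding
#'   peak detection (useful for synthetic data without impact transients).
#' @param alpha0 initial knee angle, degrees; defaults to the reference's
#'   first overlapping sample, else 0 with a warning.
#' @param calibration optional pre-computed [joint_calibration()] to
#'   reuse (skips both optimizations).
#' @return An object of class `kneeflex`; see [summary.kneeflex()],
#'   [coef.kneeflex()], [fitted.kneeflex()], [residuals.kneeflex()],
#'   [predict.kneeflex()], [plot.kneeflex()].
#' @examples
#' trial <- simulate_running_trial(duration_s = 10, seed = 42)
#' fit <- kneeflex(trial$pair, reference = trial$reference,
#'                 strikes = trial$truth$strike_indices_true)
#' summary(fit)
#' @export
kneeflex <- function(pair, reference = NULL,
                     filter = c("cf", "kf", "ekf"),
                     control = kneeflex_control(),
                     strikes = NULL, alpha0 = NULL, calibration = NULL) {
  stopifnot(inherits(pair, "sensor_pair"))
  filter <- match.arg(filter)
  ctl <- control
  dt <- 1 / pair$rate_hz
  n <- pair$n

  # 1. gait events from the unfiltered shank accelerometer
  if (is.null(strikes)) {
    strikes <- detect_foot_strikes(pair$shank$acc, pair$rate_hz,
                                   ctl$peaks_min_cycle_s,
                                   ctl$peaks_min_prominence_g)
  }
  if (length(strikes) < 2L)
    stopf("stage gait-events: need at least 2 foot strikes, found %d",
          length(strikes))
  events <- build_masks(gait_phase(strikes, n),
                        ctl$window_lo_pct, ctl$window_hi_pct,
                        ctl$gate_halfwidth_pct)
  win <- which(events$opt_mask)
  # differencing edge fill never enters the optimization window
  win <- win[win > 2L & win < n - 1L]
  if (length(win) > ctl$max_opt_samples)
    win <- win[round(seq(1L, length(win), length.out = ctl$max_opt_samples))]

  # 2. filtered signals and angular accelerations
  acc1f <- zero_lag_lowpass(pair$shank$acc, pair$rate_hz,
                            ctl$filter_cutoff_hz, ctl$filter_order)
  acc2f <- zero_lag_lowpass(pair$thigh$acc, pair$rate_hz,
                            ctl$filter_cutoff_hz, ctl$filter_order)
  gyr1f <- zero_lag_lowpass(pair$shank$gyr, pair$rate_hz,
                            ctl$filter_cutoff_hz, ctl$filter_order)
  gyr2f <- zero_lag_lowpass(pair$thigh$gyr, pair$rate_hz,
                            ctl$filter_cutoff_hz, ctl$filter_order)
  gd1 <- angular_acceleration(gyr1f, dt)
  gd2 <- angular_acceleration(gyr2f, dt)

  # 3. calibration (axes from unfiltered gyro, centres from filtered data)
  if (is.null(calibration)) {
    axes <- estimate_joint_axes(pair$shank$gyr[win, , drop = FALSE],
                                pair$thigh$gyr[win, , drop = FALSE],
                                restarts = ctl$restarts, seed = ctl$seed)
    axes <- orient_axes_flexion_positive(axes, pair$shank$gyr,
                                         pair$thigh$gyr, dt)
    centers <- estimate_joint_centers(
      acc1f[win, , drop = FALSE], acc2f[win, , drop = FALSE],
      gyr1f[win, , drop = FALSE], gyr2f[win, , drop = FALSE],
      gd1[win, , drop = FALSE], gd2[win, , drop = FALSE],
      axes$j1, axes$j2, restarts = ctl$restarts, seed = ctl$seed + 1L)
    calibration <- joint_calibration(axes, centers,
                                     sign_flipped = isTRUE(axes$sign_flipped))
  }

  # 4. raw angle measurements
  a1c <- correct_acceleration(acc1f, gyr1f, gd1, calibration$o1)
  a2c <- correct_acceleration(acc2f, gyr2f, gd2, calibration$o2)
  if (is.null(alpha0)) {
    if (!is.null(reference)) {
      alpha0 <- stats::approx(reference$t, reference$alpha,
                              xout = pair$t[1L], rule = 2L)$y
    } else {
      warnf("no reference or alpha0 supplied; initializing at 0 deg")
      alpha0 <- 0
    }
  }
  # samples inside the zero-phase filter's startup/shutdown transient are
  # not trusted as measurements (and never used to anchor the offset)
  edge <- min(ceiling(12 * pair$rate_hz / ctl$filter_cutoff_hz) + 8L, floor(n / 4))
  edge_ok <- rep(TRUE, n)
  edge_ok[c(seq_len(edge), seq.int(n - edge + 1L, n))] <- FALSE
  g1t <- project_gyro(gyr1f, calibration$j1)
  g2t <- project_gyro(gyr2f, calibration$j2)
  u <- g1t - g2t
  gyr_series <- gyro_angle(g1t, g2t, dt, alpha0 = alpha0)
  gyr_series$t <- pair$t

  if (is.null(calibration$alpha_ref_raw) || !is.null(reference)) {
    calibration$alpha_ref_raw <- NULL
    calibration$alpha_offset <- 0
    acc_raw <- accel_angle(a1c, a2c, calibration, t = pair$t, eps = ctl$eps)
    acc_raw$valid <- acc_raw$valid & edge_ok
    # anchor the constant offset on the earliest mid-cycle window (40-80%
    # of the first usable cycle), where impact residue is smallest; a
    # single-sample anchor would be fragile on noisy data. The target is
    # the reference when one exists, else the (drift-free short-term)
    # gyro-integrated angle started at alpha0.
    anchor <- which(acc_raw$valid & events$opt_mask)
    if (!length(anchor)) anchor <- which(acc_raw$valid)
    if (length(anchor)) {
      anchor <- anchor[events$cycle_of_sample[anchor] ==
                         events$cycle_of_sample[anchor[1L]]]
      raw0 <- acc_raw$alpha[anchor[1L]]
      raw_anchor <- raw0 + wrap_pm180(acc_raw$alpha[anchor] - raw0)
      target <- if (!is.null(reference)) {
        stats::approx(reference$t, reference$alpha,
                      xout = pair$t[anchor], rule = 2L)$y
      } else {
        gyr_series$alpha[anchor]
      }
      calibration$alpha_ref_raw <- raw0
      calibration$alpha_offset <- stats::median(target - raw_anchor)
    }
  }
  acc_series <- accel_angle(a1c, a2c, calibration, t = pair$t, eps = ctl$eps)
  acc_series$valid <- acc_series$valid & edge_ok

  # 5. fusion with impact gating
  cfg <- filter_config(kind = filter, q = ctl$q, r_kf = ctl$r_kf,
                       r_ekf = ctl$r_ekf, lam = ctl$lam, alpha0 = alpha0,
                       p0 = ctl$p0)
  # the EKF observes the raw in-plane rotation between the sensors, so its
  # state lives in that convention; the constant anatomical offset is
  # applied on output
  ekf_shift <- calibration$alpha_offset
  trace <- switch(filter,
    kf = run_kf(u, acc_series$alpha, events$gate_mask, dt, cfg,
                z_valid = acc_series$valid),
    ekf = {
      cfg_e <- cfg; cfg_e$alpha0 <- alpha0 - ekf_shift
      tr <- run_ekf(u, attr(acc_series, "proj1"), attr(acc_series, "proj2"),
                    events$gate_mask, dt, cfg_e, z_valid = acc_series$valid)
      tr$alpha_hat <- tr$alpha_hat + ekf_shift
      tr
    },
    cf = run_cf(acc_series$alpha, gyr_series$alpha, events$gate_mask, dt,
                cfg, z_valid = acc_series$valid))
  fused <- angle_series(pair$t, trace$alpha_hat, source = filter)

  fit <- structure(list(
    calibration = calibration, events = events,
    angles = list(gyro = gyr_series, accel = acc_series, fused = fused),
    trace = trace, filter = filter, config = cfg, control = ctl,
    reference = reference, rate_hz = pair$rate_hz, n = n, t = pair$t,
    internals = list(u = u, gate = events$gate_mask,
                     valid = acc_series$valid, dt = dt, alpha0 = alpha0,
                     proj1 = attr(acc_series, "proj1"),
                     proj2 = attr(acc_series, "proj2")),
    call = match.call()), class = "kneeflex")
  if (!is.null(reference)) {
    paired <- align_to_reference(fused, reference)
    fit$eval <- list(rmse_deg = rmse(paired), pearson_r = pearson(paired),
                     n_samples = nrow(paired))
  }
  fit
}

# rebuild the fused series with one tuning parameter changed
refit_filter <- function(fit, filter, param) {
  it <- fit$internals
  cfg <- fit$config
  cfg$kind <- filter
  if (filter == "cf") cfg$lam <- param else cfg$q <- param
  shift <- fit$calibration$alpha_offset
  trace <- switch(filter,
    kf = run_kf(it$u, fit$angles$accel$alpha, it$gate, it$dt, cfg,
                z_valid = it$valid),
    ekf = {
      cfg$alpha0 <- cfg$alpha0 - shift
      tr <- run_ekf(it$u, it$proj1, it$proj2, it$gate, it$dt, cfg,
                    z_valid = it$valid)
      tr$alpha_hat <- tr$alpha_hat + shift
      tr
    },
    cf = run_cf(fit$angles$accel$alpha, fit$angles$gyro$alpha, it$gate,
                it$dt, cfg, z_valid = it$valid))
  angle_series(fit$t, trace$alpha_hat, source = filter)
}

#' @export
print.kneeflex <- function(x, ...) {
  cat(sprintf("Knee flexion fit (%s filter), %d samples @ %g Hz\n",
              toupper(x$filter), x$n, x$rate_hz))
  cat(sprintf("  %d foot strikes; fused angle range [%.1f, %.1f] deg\n",
              length(x$events$strikes), min(x$angles$fused$alpha),
              max(x$angles$fused$alpha)))
  if (!is.null(x$eval))
    cat(sprintf("  vs reference: RMSE %.2f deg, Pearson r %.4f (n=%d)\n",
                x$eval$rmse_deg, x$eval$pearson_r, x$eval$n_samples))
  invisible(x)
}

#' Summarise a kneeflex fit
#' @param object a `kneeflex` object.
#' @param ... unused.
#' @export
summary.kneeflex <- function(object, ...) {
  out <- list(filter = object$filter, calibration = object$calibration,
              n = object$n, rate_hz = object$rate_hz,
              n_strikes = length(object$events$strikes),
              opt_window_pct = 100 * mean(object$events$opt_mask),
              gate_open_pct = 100 * mean(object$events$gate_mask),
              valid_accel_pct = 100 * mean(object$angles$accel$valid),
              eval = object$eval)
  class(out) <- "summary.kneeflex"
  out
}

#' @export
print.summary.kneeflex <- function(x, ...) {
  cat(sprintf("Knee flexion angle estimation (%s filter)\n", toupper(x$filter)))
  cat(sprintf("%d samples @ %g Hz, %d foot strikes\n", x$n, x$rate_hz,
              x$n_strikes))
  cat(sprintf("optimization window %.1f%% of samples; update gate open %.1f%%; accel angle valid %.1f%%\n",
              x$opt_window_pct, x$gate_open_pct, x$valid_accel_pct))
  print(x$calibration)
  if (!is.null(x$eval))
    cat(sprintf("Accuracy vs reference: RMSE %.2f deg, Pearson r %.4f (n=%d)\n",
                x$eval$rmse_deg, x$eval$pearson_r, x$eval$n_samples))
  invisible(x)
}

#' Calibration coefficients of a fit
#' @param object a `kneeflex` object.
#' @param ... unused.
#' @return Named vector: spherical axis parameters (rad), axis and centre
#'   components, and the accelerometer angle offset (deg).
#' @export
coef.kneeflex <- function(object, ...) {
  cl <- object$calibration
  c(phi1 = cl$phi1, theta1 = cl$theta1, phi2 = cl$phi2, theta2 = cl$theta2,
    j1 = cl$j1, j2 = cl$j2, o1 = cl$o1, o2 = cl$o2,
    alpha_offset = cl$alpha_offset)
}

#' @export
fitted.kneeflex <- function(object, ...) object$angles$fused

#' Residuals against the reference
#' @param object a `kneeflex` fitted with a reference.
#' @param ... unused.
#' @return Numeric vector (estimate minus reference, degrees) on the
#'   reference timeline.
#' @export
residuals.kneeflex <- function(object, ...) {
  if (is.null(object$reference)) stopf("fit has no reference series")
  paired <- align_to_reference(object$angles$fused, object$reference)
  structure(paired$est - paired$ref, t = paired$t)
}

#' Apply a fitted calibration to a new recording
#'
#' Reuses the fit's joint calibration and filter settings on a new
#' sensor pair from the same mounting session.
#'
#' @param object a `kneeflex` object.
#' @param pair new [sensor_pair()].
#' @param ... passed to [kneeflex()] (e.g. `reference`, `strikes`,
#'   `alpha0`).
#' @return A new `kneeflex` fit.
#' @export
predict.kneeflex <- function(object, pair, ...) {
  kneeflex(pair, filter = object$filter, control = object$control,
           calibration = object$calibration, ...)
}

#' Plot a kneeflex fit
#'
#' Overlays the fused estimate with the raw gyroscope and accelerometer
#' angles (and the reference, if present) over a time window.
#'
#' @param x a `kneeflex` object.
#' @param tlim optional length-2 time window, s.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kneeflex <- function(x, tlim = NULL, ...) {
  tt <- x$t
  sel <- if (is.null(tlim)) rep(TRUE, length(tt)) else tt >= tlim[1L] & tt <= tlim[2L]
  acc <- x$angles$accel
  ylim <- range(x$angles$fused$alpha[sel], x$angles$gyro$alpha[sel],
                if (!is.null(x$reference)) x$reference$alpha, finite = TRUE)
  graphics::plot(tt[sel], x$angles$fused$alpha[sel], type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "knee flexion (deg)",
                 ylim = ylim, col = "black", ...)
  graphics::lines(tt[sel], x$angles$gyro$alpha[sel], col = "steelblue")
  ok <- sel & acc$valid
  graphics::lines(tt[ok], acc$alpha[ok], col = "grey60")
  leg <- c(toupper(x$filter), "gyro", "accel")
  cols <- c("black", "steelblue", "grey60")
  if (!is.null(x$reference)) {
    graphics::lines(x$reference$t, x$reference$alpha, col = "firebrick",
                    lty = 2)
    leg <- c(leg, "reference"); cols <- c(cols, "firebrick")
  }
  graphics::legend("topright", legend = leg, col = cols, lty = 1, bty = "n")
  invisible(x)
}
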