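#' Align an estimate to a reference timeline
#'
#' Linearly interpolates the estimated angle onto the reference timeline
#' (the natural direction when a 400 Hz IMU estimate is scored against a
#' 200 Hz motion-capture reference). Samples outside the overlap, and
#' reference samples bracketed by any invalid estimate sample, are
#' dropped.
#'
#' @param est,ref [angle_series()] objects.
#' @return A data frame with columns `t`, `est`, `ref`.
#' @export
align_to_reference <- function(est, ref) {
  stopifnot(inherits(est, "angle_series"), inherits(ref, "angle_series"))
  lo <- max(min(est$t), min(ref$t))
  hi <- min(max(est$t), max(ref$t))
  if (lo > hi) stopf("estimate and reference time ranges do not overlap")
  keep <- ref$t >= lo & ref$t <= hi & ref$valid
  tt <- ref$t[keep]
  vals <- stats::approx(est$t, est$alpha, xout = tt, rule = 1L)$y
  ok_est <- stats::approx(est$t, as.numeric(est$valid), xout = tt,
                          method = "constant", f = 0, rule = 2L)$y > 0.5 &
    stats::approx(est$t, as.numeric(est$valid), xout = tt,
                  method = "constant", f = 1, rule = 2L)$y > 0.5
  keep2 <- is.finite(vals) & ok_est
  data.frame(t = tt[keep2], est = vals[keep2], ref = ref$alpha[keep][keep2])
}

#' Root-mean-square error of paired angles
#' @param paired data frame from [align_to_reference()] (columns `est`,
#'   `ref`).
#' @return RMSE in degrees.
#' @export
rmse <- function(paired) {
  if (nrow(paired) < 1L) stopf("no pairs")
  sqrt(mean((paired$est - paired$ref)^2))
}

#' Pearson correlation of paired angles
#' @param paired as in [rmse()]; needs >= 2 pairs and nonzero variance.
#' @return Product-moment correlation coefficient.
#' @export
pearson <- function(paired) {
  if (nrow(paired) < 2L) stopf("need at least 2 pairs")
  if (stats::sd(paired$est) == 0 || stats::sd(paired$ref) == 0)
    stopf("zero variance in paired series")
  stats::cor(paired$est, paired$ref)
}

#' Filter-parameter tuning sweep
#'
#' Re-runs the fusion filter of a fitted [kneeflex()] model over a grid of
#' tuning-parameter values (lambda for the CF, process noise q for the
#' KF/EKF), reusing the calibration and raw angle measurements, and scores
#' each against the model's reference. Reproduces the characteristic
#' U-shaped RMSE-vs-parameter curve: too little measurement weight leaves
#' gyroscope drift uncorrected, too much admits accelerometer noise.
#'
#' @param fit a `kneeflex` object fitted with a reference.
#' @param param_grid numeric vector of parameter values.
#' @param filter filter kind; defaults to the fitted one.
#' @return Data frame with columns `param`, `rmse`; the attribute
#'   `"best"` holds the argmin row (ties broken toward the smaller value).
#' @export
tune_sweep <- function(fit, param_grid, filter = NULL) {
  stopifnot(inherits(fit, "kneeflex"))
  if (!length(param_grid)) stopf("empty parameter grid")
  if (is.null(fit$reference)) stopf("tuning needs a reference angle series")
  if (is.null(filter)) filter <- fit$filter
  param_grid <- sort(as.numeric(param_grid))
  rms <- vapply(param_grid, function(p) {
    f2 <- refit_filter(fit, filter, p)
    rmse(align_to_reference(f2, fit$reference))
  }, numeric(1L))
  out <- data.frame(param = param_grid, rmse = rms)
  attr(out, "best") <- out[which.min(rms), ]
  out
}

#' Per-cycle ensemble summary
#'
#' Resamples each complete gait cycle of one or more estimates onto a
#' common 101-point 0-100% phase grid and reports per-grid-point mean and
#' standard deviation, plus the reference mean and a 95% interval
#' (mean +/- 1.96 sd across cycles).
#'
#' @param est_list named list of [angle_series()] estimates.
#' @param ref reference [angle_series()] (same timeline family).
#' @param strikes strike sample indices on the estimates' timeline.
#' @param grid_pts number of phase grid points.
#' @return Data frame with `phase_pct`, then `<name>_mean`, `<name>_sd`
#'   per estimator, and `ref_mean`, `ref_lo`, `ref_hi`.
#' @export
cycle_ensemble <- function(est_list, ref, strikes, grid_pts = 101L) {
  if (length(strikes) < 3L) stopf("need at least 2 complete cycles")
  grid <- seq(0, 100, length.out = grid_pts)
  resample <- function(x) {
    # rows: cycles, cols: grid
    out <- matrix(NA_real_, length(strikes) - 1L, grid_pts)
    for (i in seq_len(length(strikes) - 1L)) {
      k <- strikes[i]:strikes[i + 1L]
      ph <- 100 * (k - strikes[i]) / (strikes[i + 1L] - strikes[i])
      out[i, ] <- stats::approx(ph, x[k], xout = grid)$y
    }
    out
  }
  res <- data.frame(phase_pct = grid)
  for (nm in names(est_list)) {
    M <- resample(est_list[[nm]]$alpha)
    res[[paste0(nm, "_mean")]] <- colMeans(M)
    res[[paste0(nm, "_sd")]] <- apply(M, 2L, stats::sd)
  }
  Mr <- resample(ref$alpha)
  mu <- colMeans(Mr); sdv <- apply(Mr, 2L, stats::sd)
  res$ref_mean <- mu
  res$ref_lo <- mu - 1.96 * sdv
  res$ref_hi <- mu + 1.96 * sdv
  res
}
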