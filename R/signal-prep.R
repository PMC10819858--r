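#' Angular acceleration by five-point central differencing
#'
#' Differentiates a gyroscope stream with the fourth-order-accurate
#' five-point central stencil
#' \deqn{\dot g(t) = [g(t-2\Delta t) - 8 g(t-\Delta t) + 8 g(t+\Delta t) -
#'   g(t+2\Delta t)] / (12 \Delta t),}
#' exact for polynomials up to degree four. The first and last two samples
#' are filled with one-sided differences of matching order and flagged in
#' the `"edge_filled"` attribute.
#'
#' @param gyr numeric vector or n x 3 matrix, rad/s.
#' @param dt sample interval, s.
#' @return Same shape as `gyr`, rad/s^2, with attribute `edge_filled`
#'   giving the filled sample indices.
#' @export
angular_acceleration <- function(gyr, dt) {
  vec <- is.null(dim(gyr))
  G <- if (vec) matrix(gyr, ncol = 1L) else as.matrix(gyr)
  n <- nrow(G)
  if (n < 5L) stopf("angular_acceleration needs at least 5 samples, got %d", n)
  D <- matrix(NA_real_, n, ncol(G))
  i <- 3:(n - 2L)
  D[i, ] <- (G[i - 2L, , drop = FALSE] - 8 * G[i - 1L, , drop = FALSE] +
               8 * G[i + 1L, , drop = FALSE] - G[i + 2L, , drop = FALSE]) /
    (12 * dt)
  # one-sided 5-point stencils, 4th-order accurate
  fwd <- c(-25, 48, -36, 16, -3) / (12 * dt)
  for (k in 1:2) {
    D[k, ] <- fwd %*% G[k:(k + 4L), , drop = FALSE]
    D[n - k + 1L, ] <- -fwd %*% G[(n - k + 1L):(n - k - 3L), , drop = FALSE]
  }
  out <- if (vec) drop(D) else D
  attr(out, "edge_filled") <- c(1L, 2L, n - 1L, n)
  out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and
#' backward (zero net phase; the effective magnitude response is the
#' squared single-pass response). Defaults follow the running-gait
#' pipeline: 4th order, 7 Hz cutoff.
#'
#' @param x numeric vector or n x 3 matrix.
#' @param rate_hz sample rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order for the single pass.
#' @return Filtered series, same shape and length as `x`.
#' @export
zero_lag_lowpass <- function(x, rate_hz, cutoff_hz = 7, order = 4) {
  if (cutoff_hz >= rate_hz / 2)
    stopf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, rate_hz / 2)
  bf <- signal::butter(order, 2 * cutoff_hz / rate_hz, type = "low")
  apply_ff <- function(v) {
    # reflect-pad to suppress edge transients, then forward-backward filter
    npad <- min(length(v) - 1L, 12L * ceiling(rate_hz / cutoff_hz))
    lead <- 2 * v[1L] - v[(npad + 1L):2L]
    tail <- 2 * v[length(v)] - v[(length(v) - 1L):(length(v) - npad)]
    vp <- c(lead, v, tail)
    f1 <- rev(signal::filter(bf, rev(signal::filter(bf, vp))))
    f1[(npad + 1L):(npad + length(v))]
  }
  if (is.null(dim(x))) apply_ff(as.numeric(x)) else apply(as.matrix(x), 2L, apply_ff)
}

#' Detect foot strikes from the unfiltered shank accelerometer
#'
#' Foot-strike impacts during running dominate the shank acceleration, so
#' strikes are located as prominent local maxima of the unfiltered
#' acceleration norm, with a refractory spacing that enforces a minimum
#' gait-cycle duration. When two candidate peaks fall closer than the
#' spacing, the larger is kept.
#'
#' @param acc n x 3 matrix of unfiltered shank acceleration, m/s^2 (a
#'   pre-computed norm vector is also accepted).
#' @param rate_hz sample rate, Hz.
#' @param min_cycle_s minimum strike-to-strike interval, s.
#' @param min_prominence_g minimum peak prominence, in g.
#' @return Integer vector of strike sample indices, sorted increasing
#'   (possibly empty, with a warning).
#' @export
detect_foot_strikes <- function(acc, rate_hz, min_cycle_s = 0.4,
                                min_prominence_g = 4) {
  mag <- if (is.null(dim(acc))) as.numeric(acc) else row_norms(as.matrix(acc))
  n <- length(mag)
  if (n == 0L) stopf("empty recording")
  min_prom <- min_prominence_g * GRAVITY
  # strict local maxima (plateaus: leftmost sample)
  is_peak <- which(diff(sign(diff(mag))) < 0) + 1L
  if (length(is_peak)) {
    prom <- vapply(is_peak, function(i) {
      h <- mag[i]
      # walk out to the nearest higher sample on each side; prominence is
      # the drop to the higher of the two intervening minima
      left <- mag[seq_len(i - 1L)]
      right <- mag[seq.int(i + 1L, n)]
      hl <- which(left > h)
      lmin <- if (length(hl)) min(left[(max(hl) + 1L):(i - 1L)]) else min(left)
      hr <- which(right > h)
      rmin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)]) else min(right)
      h - max(lmin, rmin)
    }, numeric(1L))
    is_peak <- is_peak[prom >= min_prom]
  }
  # enforce spacing, keeping larger peaks first
  if (length(is_peak) > 1L) {
    keep <- logical(length(is_peak))
    ord <- order(mag[is_peak], decreasing = TRUE)
    taken <- integer(0L)
    min_gap <- min_cycle_s * rate_hz
    for (i in ord) {
      if (!length(taken) || all(abs(is_peak[i] - is_peak[taken]) >= min_gap)) {
        keep[i] <- TRUE
        taken <- c(taken, i)
      }
    }
    is_peak <- is_peak[keep]
  }
  if (!length(is_peak)) warnf("no foot strikes detected")
  sort(is_peak)
}

#' Gait-cycle phase from foot strikes
#'
#' Assigns each sample a gait-cycle index and a within-cycle phase
#' percentage: phase is 0 at a strike and approaches 100 just before the
#' next strike. Samples before the first or at/after the last strike get
#' cycle index -1 and phase `NA`.
#'
#' @param strikes strictly increasing strike sample indices (>= 2).
#' @param n_samples total number of samples.
#' @return Object of class `gait_events` with fields `strikes`,
#'   `cycle_of_sample`, `phase_pct`, `n_samples` (masks unfilled; see
#'   [build_masks()]).
#' @export
gait_phase <- function(strikes, n_samples) {
  strikes <- as.integer(strikes)
  if (length(strikes) < 2L) stopf("gait_phase needs at least 2 strikes")
  if (any(diff(strikes) <= 0L)) stopf("strikes must be strictly increasing")
  if (strikes[1L] < 1L || strikes[length(strikes)] > n_samples)
    stopf("strikes out of range 1..%d", n_samples)
  cyc <- rep(-1L, n_samples)
  ph <- rep(NA_real_, n_samples)
  for (i in seq_len(length(strikes) - 1L)) {
    k <- strikes[i]:(strikes[i + 1L] - 1L)
    cyc[k] <- i
    ph[k] <- 100 * (k - strikes[i]) / (strikes[i + 1L] - strikes[i])
  }
  structure(list(strikes = strikes, cycle_of_sample = cyc, phase_pct = ph,
                 n_samples = as.integer(n_samples),
                 opt_mask = NULL, gate_mask = NULL),
            class = "gait_events")
}

#' Optimization-window and update-gate masks
#'
#' Fills the two boolean masks driving the pipeline: `opt_mask` selects the
#' mid-cycle window (default 40-80% of each gait cycle) used by the axis
#' and joint-centre optimizations, and `gate_mask` marks samples where the
#' filters may apply their measurement update — it is `FALSE` within a
#' half-width (default 5% of the adjacent cycle length, in samples) on
#' either side of every strike, where foot-strike impacts corrupt the
#' accelerometer. Samples outside any complete cycle are excluded from the
#' optimization window but left update-enabled.
#'
#' @param events a `gait_events` object with phase populated.
#' @param opt_lo,opt_hi optimization window bounds, percent of cycle.
#' @param gate_halfwidth_pct gate half-width, percent of cycle length.
#' @return `events` with `opt_mask` and `gate_mask` filled.
#' @export
build_masks <- function(events, opt_lo = 40, opt_hi = 80,
                        gate_halfwidth_pct = 5) {
  stopifnot(inherits(events, "gait_events"))
  if (is.null(events$phase_pct)) stopf("phase not populated; run gait_phase first")
  n <- events$n_samples
  ph <- events$phase_pct
  events$opt_mask <- !is.na(ph) & ph >= opt_lo & ph <= opt_hi
  gate <- rep(TRUE, n)
  s <- events$strikes
  ns <- length(s)
  cyc_len <- diff(s)
  for (i in seq_len(ns)) {
    # half-width from this strike's own adjacent cycle; edge strikes borrow
    # the nearest full cycle
    len <- if (i < ns) cyc_len[i] else cyc_len[ns - 1L]
    hw <- round(gate_halfwidth_pct / 100 * len)
    lo <- max(1L, s[i] - hw); hi <- min(n, s[i] + hw)
    gate[lo:hi] <- FALSE
  }
  events$gate_mask <- gate
  events
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d strikes over %d samples", length(x$strikes),
              x$n_samples))
  if (!is.null(x$opt_mask))
    cat(sprintf("; opt window %.1f%%, gate open %.1f%%",
                100 * mean(x$opt_mask), 100 * mean(x$gate_mask)))
  cat("\n")
  invisible(x)
}
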