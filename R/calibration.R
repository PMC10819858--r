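#' Hinge-axis alignment cost
#'
#' Under the hinge assumption the relative angular velocity between shank
#' and thigh lies along a fixed axis in each sensor frame, so the
#' angular-velocity components perpendicular to the true axes have equal
#' magnitude in both sensors at every instant. The cost sums the squared
#' mismatch
#' \deqn{\Psi = \sum_k (\|g_1(t_k) \times j_1\| - \|g_2(t_k) \times j_2\|)^2}
#' over the window, with each axis parameterised by spherical coordinates
#' \eqn{j = (\cos\phi\cos\theta, \cos\phi\sin\theta, \sin\phi)}.
#'
#' @param phi1,theta1,phi2,theta2 spherical axis parameters, radians.
#' @param g1_win,g2_win n x 3 windowed gyroscope matrices, rad/s.
#' @return Non-negative scalar.
#' @export
axis_cost <- function(phi1, theta1, phi2, theta2, g1_win, g2_win) {
  sum(axis_residuals(c(phi1, theta1, phi2, theta2), g1_win, g2_win)^2)
}

axis_residuals <- function(par, g1_win, g2_win) {
  g1_win <- as.matrix(g1_win); g2_win <- as.matrix(g2_win)
  if (nrow(g1_win) == 0L || nrow(g1_win) != nrow(g2_win))
    stopf("windows must be non-empty and of equal length")
  j1 <- sph_to_unit(par[1L], par[2L])
  j2 <- sph_to_unit(par[3L], par[4L])
  J1 <- matrix(j1, nrow(g1_win), 3L, byrow = TRUE)
  J2 <- matrix(j2, nrow(g2_win), 3L, byrow = TRUE)
  row_norms(cross3_rows(g1_win, J1)) - row_norms(cross3_rows(g2_win, J2))
}

axis_jacobian <- function(par, g1_win, g2_win) {
  # d r_k / d(phi_i, theta_i):  r_k = ||g1 x j1|| - ||g2 x j2||
  jac_block <- function(G, phi, theta, sgn) {
    j <- sph_to_unit(phi, theta)
    djp <- c(-sin(phi) * cos(theta), -sin(phi) * sin(theta), cos(phi))
    djt <- c(-cos(phi) * sin(theta), cos(phi) * cos(theta), 0)
    J <- matrix(j, nrow(G), 3L, byrow = TRUE)
    cx <- cross3_rows(G, J)
    nrm <- pmax(row_norms(cx), 1e-300)
    dp <- rowSums(cx * cross3_rows(G, matrix(djp, nrow(G), 3L, byrow = TRUE))) / nrm
    dt <- rowSums(cx * cross3_rows(G, matrix(djt, nrow(G), 3L, byrow = TRUE))) / nrm
    sgn * cbind(dp, dt)
  }
  cbind(jac_block(g1_win, par[1L], par[2L], 1),
        jac_block(g2_win, par[3L], par[4L], -1))
}

#' Estimate the knee-axis direction in both sensor frames
#'
#' Minimises [axis_cost()] by damped (Levenberg-Marquardt) nonlinear least
#' squares over the four spherical parameters, from several seeded random
#' starting axes, keeping the best converged fit. The inherent sign
#' ambiguity (the cost is invariant under \eqn{j_i \to -j_i}) is resolved
#' deterministically: `j2` is flipped if the windowed projected rates
#' `g1.j1` and `g2.j2` correlate negatively, and callers fix the remaining
#' joint flip via the flexion-positive convention (see
#' [orient_axes_flexion_positive()]).
#'
#' @param g1_win,g2_win windowed gyroscope data (rows where the
#'   optimization mask is true), rad/s.
#' @param restarts number of random initialisations.
#' @param seed integer seed for the restarts.
#' @return List with `phi1, theta1, phi2, theta2`, unit axes `j1`, `j2`,
#'   and `final_cost`.
#' @export
estimate_joint_axes <- function(g1_win, g2_win, restarts = 10L, seed = 1L) {
  g1_win <- as.matrix(g1_win); g2_win <- as.matrix(g2_win)
  if (nrow(g1_win) < 8L) stopf("too few window samples (%d)", nrow(g1_win))
  if (stats::sd(row_norms(g1_win)) < 1e-10 && mean(row_norms(g1_win)) < 1e-8)
    stopf("degenerate window: near-zero angular velocity")
  set.seed(as.integer(seed))
  starts <- replicate(restarts, {
    v1 <- stats::rnorm(3L); v2 <- stats::rnorm(3L)
    c(unit_to_sph(v1), unit_to_sph(v2))
  })
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[, r], fn = axis_residuals,
                         jac = axis_jacobian,
                         g1_win = g1_win, g2_win = g2_win,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200L, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cost <- sum(fit$fvec^2)
    if (is.null(best) || cost < best$cost - 1e-15) best <- list(par = fit$par, cost = cost)
    if (best$cost < 1e-12) break  # numerically exact fit; restarts cannot improve
  }
  if (is.null(best)) stopf("axis estimation failed to converge from any restart")
  par <- best$par
  j1 <- sph_to_unit(par[1L], par[2L])
  j2 <- sph_to_unit(par[3L], par[4L])
  # sign disambiguation between the two axes
  p1 <- g1_win %*% j1; p2 <- g2_win %*% j2
  if (sum(p1 * p2) < 0) {
    j2 <- -j2
    par[3:4] <- unit_to_sph(j2)
  }
  list(phi1 = unname(par[1L]), theta1 = unname(par[2L]),
       phi2 = unname(par[3L]), theta2 = unname(par[4L]),
       j1 = unname(j1), j2 = unname(j2), final_cost = best$cost)
}

#' Lever-arm (rotational) acceleration term
#'
#' The acceleration a sensor picks up because it sits a lever arm `o` away
#' from the joint centre: the centripetal term \eqn{g \times (g \times o)}
#' plus the tangential term \eqn{\dot g \times o}.
#'
#' @param g angular velocity 3-vector (or n x 3 matrix), rad/s.
#' @param gdot angular acceleration, rad/s^2, same shape.
#' @param o lever-arm 3-vector, m.
#' @return Same shape as `g`, m/s^2.
#' @export
rotational_acc_term <- function(g, gdot, o) {
  if (is.null(dim(g))) return(cross3(g, cross3(g, o)) + cross3(gdot, o))
  O <- matrix(o, nrow(g), 3L, byrow = TRUE)
  cross3_rows(g, cross3_rows(g, O)) + cross3_rows(gdot, O)
}

#' Joint-centre localisation cost
#'
#' After removing each sensor's lever-arm term, both sensors must measure
#' the specific force of the common joint centre, so the corrected
#' acceleration norms agree:
#' \deqn{\tilde\Psi = \sum_k (\|a_1 - \Gamma(g_1)(\hat o_1)\| -
#'   \|a_2 - \Gamma(g_2)(\hat o_2)\|)^2.}
#'
#' @param o1hat,o2hat candidate joint-centre positions, m, sensor frames.
#' @param a1_win,a2_win windowed (filtered) accelerations, m/s^2.
#' @param g1_win,g2_win windowed (filtered) gyroscopes, rad/s.
#' @param g1dot_win,g2dot_win windowed angular accelerations, rad/s^2.
#' @return Non-negative scalar.
#' @export
center_cost <- function(o1hat, o2hat, a1_win, a2_win, g1_win, g2_win,
                        g1dot_win, g2dot_win) {
  sum(center_residuals(c(o1hat, o2hat), a1_win, a2_win, g1_win, g2_win,
                       g1dot_win, g2dot_win)^2)
}

center_residuals <- function(par, a1_win, a2_win, g1_win, g2_win,
                             g1dot_win, g2dot_win) {
  lens <- vapply(list(a1_win, a2_win, g1_win, g2_win, g1dot_win, g2dot_win),
                 nrow, integer(1L))
  if (lens[1L] == 0L || length(unique(lens)) != 1L)
    stopf("windows must be non-empty and of equal length")
  c1 <- a1_win - rotational_acc_term(g1_win, g1dot_win, par[1:3])
  c2 <- a2_win - rotational_acc_term(g2_win, g2dot_win, par[4:6])
  row_norms(c1) - row_norms(c2)
}

center_jacobian <- function(par, a1_win, a2_win, g1_win, g2_win,
                            g1dot_win, g2dot_win) {
  # r = ||c1|| - ||c2||, c_i = a_i - Gamma_i(o_i);
  # d r / d o_i = -sgn_i * c_i^T (gxgx + gdotx) / ||c_i||
  jac_block <- function(A, G, Gd, o, sgn) {
    C <- A - rotational_acc_term(G, Gd, o)
    nrm <- pmax(row_norms(C), 1e-300)
    out <- matrix(0, nrow(A), 3L)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- 1
      E <- matrix(e, nrow(A), 3L, byrow = TRUE)
      col <- cross3_rows(G, cross3_rows(G, E)) + cross3_rows(Gd, E)
      out[, ax] <- -sgn * rowSums(C * col) / nrm
    }
    out
  }
  cbind(jac_block(a1_win, g1_win, g1dot_win, par[1:3], 1),
        jac_block(a2_win, g2_win, g2dot_win, par[4:6], -1))
}

#' Estimate the joint-centre position in both sensor frames
#'
#' Minimises [center_cost()] over both 3-vectors jointly
#' (Levenberg-Marquardt, seeded random restarts inside a +/-0.3 m cube).
#' The component of the centre along the hinge axis is unobservable from
#' hinge motion, so the shared axial component is removed symmetrically:
#' \deqn{o_i = \hat o_i - j_i (\hat o_1 \cdot j_1 + \hat o_2 \cdot j_2)/2,}
#' after which the recomputed mean axial component is exactly zero.
#'
#' @param a1_win,a2_win,g1_win,g2_win,g1dot_win,g2dot_win windowed filtered
#'   series as in [center_cost()].
#' @param j1,j2 unit knee-axis estimates from [estimate_joint_axes()].
#' @param restarts,seed as in [estimate_joint_axes()].
#' @return List with `o1`, `o2` (m) and `final_cost`.
#' @export
estimate_joint_centers <- function(a1_win, a2_win, g1_win, g2_win,
                                   g1dot_win, g2dot_win, j1, j2,
                                   restarts = 10L, seed = 1L) {
  set.seed(as.integer(seed))
  starts <- cbind(matrix(0, 6L, 1L),
                  matrix(stats::runif(6L * max(0L, restarts - 1L), -0.3, 0.3),
                         6L))
  # Gamma(g)(o) is linear in o: precompute its basis columns once
  lever_basis <- function(G, Gd) {
    lapply(1:3, function(ax) {
      e <- c(0, 0, 0); e[ax] <- 1
      E <- matrix(e, nrow(G), 3L, byrow = TRUE)
      cross3_rows(G, cross3_rows(G, E)) + cross3_rows(Gd, E)
    })
  }
  B1 <- lever_basis(as.matrix(g1_win), as.matrix(g1dot_win))
  B2 <- lever_basis(as.matrix(g2_win), as.matrix(g2dot_win))
  a1_win <- as.matrix(a1_win); a2_win <- as.matrix(a2_win)
  corr <- function(A, B, o) A - o[1L] * B[[1L]] - o[2L] * B[[2L]] - o[3L] * B[[3L]]
  fn_fast <- function(par) {
    row_norms(corr(a1_win, B1, par[1:3])) - row_norms(corr(a2_win, B2, par[4:6]))
  }
  jac_fast <- function(par) {
    C1 <- corr(a1_win, B1, par[1:3]); n1 <- pmax(row_norms(C1), 1e-300)
    C2 <- corr(a2_win, B2, par[4:6]); n2 <- pmax(row_norms(C2), 1e-300)
    J <- matrix(0, nrow(a1_win), 6L)
    for (ax in 1:3) {
      J[, ax] <- -rowSums(C1 * B1[[ax]]) / n1
      J[, ax + 3L] <- rowSums(C2 * B2[[ax]]) / n2
    }
    J
  }
  best <- NULL; fallback <- NULL
  for (r in seq_len(ncol(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[, r], fn = fn_fast, jac = jac_fast,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200L, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cost <- sum(fit$fvec^2)
    if (is.null(fallback) || cost < fallback$cost - 1e-15)
      fallback <- list(par = fit$par, cost = cost)
    # noise can carve spurious minima far from the joint. Only the
    # components orthogonal to the axis are observable (the axial part
    # does not enter the lever-arm term under hinge motion), so reject
    # solutions whose orthogonal lever arm is anatomically implausible.
    p1 <- fit$par[1:3] - j1 * sum(fit$par[1:3] * j1)
    p2 <- fit$par[4:6] - j2 * sum(fit$par[4:6] * j2)
    if (max(vnorm(p1), vnorm(p2)) > 0.5) next
    if (is.null(best) || cost < best$cost - 1e-15) best <- list(par = fit$par, cost = cost)
    if (best$cost < 1e-12) break
  }
  if (is.null(best) && !is.null(fallback)) {
    warnf("all joint-centre solutions have implausible lever arms (>0.5 m)")
    best <- fallback
  }
  if (is.null(best)) stopf("joint-centre estimation failed to converge")
  o1h <- best$par[1:3]; o2h <- best$par[4:6]
  axial <- (sum(o1h * j1) + sum(o2h * j2)) / 2
  list(o1 = o1h - j1 * axial, o2 = o2h - j2 * axial, final_cost = best$cost)
}

#' Remove the lever-arm term from an acceleration stream
#'
#' \deqn{\tilde a(t) = a(t) - \Gamma(g(t))(o)} per sample, so the sensor
#' reports the specific force of the joint centre rather than of its own
#' mounting point.
#'
#' @param a n x 3 acceleration, m/s^2.
#' @param g n x 3 angular velocity, rad/s.
#' @param gdot n x 3 angular acceleration, rad/s^2.
#' @param o joint-centre 3-vector, m.
#' @return n x 3 corrected acceleration, m/s^2.
#' @export
correct_acceleration <- function(a, g, gdot, o) {
  as.matrix(a) - rotational_acc_term(as.matrix(g), as.matrix(gdot), o)
}

#' Assemble a joint calibration
#'
#' Combines estimated axes and centres with the in-plane reference bases
#' used by the accelerometer angle: \eqn{x_i = j_i \times c},
#' \eqn{y_i = j_i \times x_i} with reference vector `c = (1,0,0)` (swapped
#' to `(0,1,0)` when an axis is nearly parallel to it).
#'
#' @param axes result of [estimate_joint_axes()].
#' @param centers result of [estimate_joint_centers()].
#' @param c_vec in-plane reference vector.
#' @param sign_flipped whether the flexion-positive convention flipped both
#'   axes (bookkeeping; see [orient_axes_flexion_positive()]).
#' @param alpha_offset constant offset added to the accelerometer angle,
#'   degrees.
#' @return Object of class `joint_calibration`.
#' @export
joint_calibration <- function(axes, centers, c_vec = c(1, 0, 0),
                              sign_flipped = FALSE, alpha_offset = 0) {
  fallback <- FALSE
  if (max(abs(sum(axes$j1 * c_vec)), abs(sum(axes$j2 * c_vec))) > 0.999) {
    c_vec <- c(0, 1, 0)
    fallback <- TRUE
  }
  x1 <- cross3(axes$j1, c_vec); y1 <- cross3(axes$j1, x1)
  x2 <- cross3(axes$j2, c_vec); y2 <- cross3(axes$j2, x2)
  structure(list(phi1 = axes$phi1, theta1 = axes$theta1,
                 phi2 = axes$phi2, theta2 = axes$theta2,
                 j1 = axes$j1, j2 = axes$j2,
                 o1 = centers$o1, o2 = centers$o2,
                 c_vec = c_vec, c_fallback = fallback,
                 x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 sign_flipped = sign_flipped,
                 alpha_offset = alpha_offset,
                 axis_cost = axes$final_cost,
                 center_cost = centers$final_cost),
            class = "joint_calibration")
}

#' Fix the global axis sign by the flexion-positive convention
#'
#' The axis pair is only determined up to a joint flip
#' \eqn{(j_1, j_2) \to (-j_1, -j_2)}, which negates both the
#' gyroscope-integrated and the accelerometer-derived angle. The branch is
#' fixed so that the integrated relative angle has predominantly positive
#' excursion (knee flexion positive): if the mean of the zero-initialised
#' gyro angle over the dataset is negative, both axes are flipped.
#'
#' @param axes result of [estimate_joint_axes()].
#' @param g1,g2 full (unfiltered) gyroscope streams, rad/s.
#' @param dt sample interval, s.
#' @return `axes`, possibly with both axes flipped, plus `sign_flipped`.
#' @export
orient_axes_flexion_positive <- function(axes, g1, g2, dt) {
  diff_rate <- as.matrix(g1) %*% axes$j1 - as.matrix(g2) %*% axes$j2
  alpha <- cumtrapz_scalar(drop(diff_rate), dt)
  flipped <- mean(alpha) < 0
  if (flipped) {
    axes$j1 <- -axes$j1; axes$j2 <- -axes$j2
    s1 <- unit_to_sph(axes$j1); s2 <- unit_to_sph(axes$j2)
    axes$phi1 <- s1[1L]; axes$theta1 <- s1[2L]
    axes$phi2 <- s2[1L]; axes$theta2 <- s2[2L]
  }
  axes$sign_flipped <- flipped
  axes
}

#' @export
print.joint_calibration <- function(x, ...) {
  cat("<joint_calibration>\n")
  cat(sprintf("  j1 (shank): [%7.4f %7.4f %7.4f]   j2 (thigh): [%7.4f %7.4f %7.4f]\n",
              x$j1[1L], x$j1[2L], x$j1[3L], x$j2[1L], x$j2[2L], x$j2[3L]))
  cat(sprintf("  o1 (m):     [%7.4f %7.4f %7.4f]   o2 (m):     [%7.4f %7.4f %7.4f]\n",
              x$o1[1L], x$o1[2L], x$o1[3L], x$o2[1L], x$o2[2L], x$o2[3L]))
  cat(sprintf("  axis cost %.3e, centre cost %.3e%s%s\n",
              x$axis_cost, x$center_cost,
              if (x$sign_flipped) ", axes flipped to flexion-positive" else "",
              if (x$c_fallback) ", c-vector fallback (0,1,0)" else ""))
  invisible(x)
}

#' Serialize / restore a calibration
#'
#' Calibrations are tied to a mounting session and can be reused across
#' recordings from the same session.
#'
#' @param calib a `joint_calibration`.
#' @param path file path for the JSON document.
#' @return `read_calibration` returns a `joint_calibration`.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "joint_calibration"))
  obj <- unclass(calib)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "joint_calibration")
}
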