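# internal geometry / unit helpers

GRAVITY <- 9.80665  # m/s^2
G_PER_MS2 <- 1 / GRAVITY

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# row-wise cross product of n x 3 matrices
cross3_rows <- function(U, V) {
  cbind(U[, 2L] * V[, 3L] - U[, 3L] * V[, 2L],
        U[, 3L] * V[, 1L] - U[, 1L] * V[, 3L],
        U[, 1L] * V[, 2L] - U[, 2L] * V[, 1L])
}

vnorm <- function(v) sqrt(sum(v^2))

row_norms <- function(M) sqrt(rowSums(M^2))

# rotation about z by angle (rad)
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

# Rodrigues rotation matrix: axis (unit), angle (rad)
rot_axis_angle <- function(axis, angle) {
  axis <- axis / vnorm(axis)
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

# spherical parameterisation of a unit vector (Eq. used by the axis search):
# j = (cos(phi) cos(theta), cos(phi) sin(theta), sin(phi))
sph_to_unit <- function(phi, theta) {
  c(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
}

unit_to_sph <- function(j) {
  j <- j / vnorm(j)
  c(phi = asin(max(-1, min(1, j[3L]))), theta = atan2(j[2L], j[1L]))
}

# wrap an angle (deg) into (-180, 180]
wrap_pm180 <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y <= -180] <- 180
  y
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
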