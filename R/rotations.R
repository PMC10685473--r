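#' Elementary rotation matrices
#'
#' Right-handed rotation matrices about the x, y and z axes. Angles are in
#' degrees, matching the convention used throughout the package for joint
#' angles and segment-axis offsets.
#'
#' @param angle rotation angle in degrees
#' @return a 3x3 rotation matrix
#' @name elementary-rotations
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @rdname elementary-rotations
#' @export
rot_x <- function(angle) {
  a <- deg2rad(angle)
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0,
           0, ca, sa,
           0, -sa, ca), 3L, 3L)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(angle) {
  a <- deg2rad(angle)
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa,
           0, 1, 0,
           sa, 0, ca), 3L, 3L)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(angle) {
  a <- deg2rad(angle)
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0,
           -sa, ca, 0,
           0, 0, 1), 3L, 3L)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Compose a rotation from x-z-y Cardan angles
#'
#' Builds `R = Rx(alpha) %*% Rz(beta) %*% Ry(gamma)`, the rotation whose
#' x-z-y Cardan decomposition is the given angle triple. This is the
#' intersegmental angle convention used by the foot model: the first
#' rotation (about x) is the sagittal-plane component, the second (about z)
#' the frontal-plane component, the third (about y) the transverse-plane
#' component.
#'
#' @param alpha_x,beta_z,gamma_y Cardan angles in degrees
#' @return a 3x3 rotation matrix
#' @seealso [cardan_xzy()]
#' @export
cardan_compose <- function(alpha_x, beta_z, gamma_y) {
  rot_x(alpha_x) %*% rot_z(beta_z) %*% rot_y(gamma_y)
}

#' Extract x-z-y Cardan angles from a rotation
#'
#' Decomposes a relative orientation into the ordered rotation sequence
#' x (sagittal), z (frontal), y (transverse):
#' `R = Rx(alpha) %*% Rz(beta) %*% Ry(gamma)`.
#' The frontal angle is confined to (-90, 90) degrees; a warning is issued
#' when it comes within `gimbal_tol` degrees of the gimbal singularity at
#' +/-90, where the sagittal and transverse angles become ill-conditioned.
#'
#' @param R a 3x3 rotation matrix (orthonormal, determinant +1)
#' @param gimbal_tol proximity to +/-90 degrees (in degrees) that triggers a
#'   gimbal warning
#' @return named numeric vector `c(alpha_x, beta_z, gamma_y)` in degrees
#' @export
cardan_xzy <- function(R, gimbal_tol = 0.1) {
  if (!is_rotation(R)) {
    stop("cardan_xzy: input is not an orthonormal rotation matrix (det +1)")
  }
  s_beta <- -R[1L, 2L]
  s_beta <- max(-1, min(1, s_beta))
  beta <- asin(s_beta)
  if (90 - abs(rad2deg(beta)) < gimbal_tol) {
    warning("cardan_xzy: frontal angle within ", gimbal_tol,
            " degrees of gimbal singularity; sagittal/transverse angles unreliable")
  }
  alpha <- atan2(R[3L, 2L], R[2L, 2L])
  gamma <- atan2(R[1L, 3L], R[1L, 1L])
  c(alpha_x = rad2deg(alpha), beta_z = rad2deg(beta), gamma_y = rad2deg(gamma))
}

#' Relative rotation series between two segment poses
#'
#' Intersegmental motion is expressed as the distal (child) segment relative
#' to the proximal (parent) segment: `R_rel(t) = t(R_parent(t)) %*% R_child(t)`.
#'
#' @param child,parent `segment_pose` objects (see [pose_time_series()]) with
#'   equal frame counts
#' @return a 3x3xT array of relative rotations; frames gapped in either input
#'   are NA
#' @export
relative_rotation <- function(child, parent) {
  stopifnot(inherits(child, "segment_pose"), inherits(parent, "segment_pose"))
  nt <- dim(child$R)[3L]
  if (dim(parent$R)[3L] != nt) {
    stop("relative_rotation: child and parent have different frame counts")
  }
  out <- array(NA_real_, c(3L, 3L, nt))
  gap <- child$gap | parent$gap
  for (t in seq_len(nt)) {
    if (!gap[t]) out[, , t] <- crossprod(parent$R[, , t], child$R[, , t])
  }
  attr(out, "gap") <- gap
  out
}

# Angular velocity (rad/s, lab frame) of an orientation series by central
# differences of R: omega_skew = Rdot %*% t(R). End frames use one-sided
# differences so output length equals input length.
angular_velocity <- function(R, rate) {
  nt <- dim(R)[3L]
  if (nt < 3L) stop("angular_velocity: need at least 3 frames")
  omega <- matrix(NA_real_, nt, 3L)
  dt <- 1 / rate
  for (t in seq_len(nt)) {
    if (t == 1L) {
      Rdot <- (R[, , 2L] - R[, , 1L]) / dt
      Rt <- R[, , 1L]
    } else if (t == nt) {
      Rdot <- (R[, , nt] - R[, , nt - 1L]) / dt
      Rt <- R[, , nt]
    } else {
      Rdot <- (R[, , t + 1L] - R[, , t - 1L]) / (2 * dt)
      Rt <- R[, , t]
    }
    S <- Rdot %*% t(Rt)
    S <- (S - t(S)) / 2
    omega[t, ] <- c(S[3L, 2L], S[1L, 3L], S[2L, 1L])
  }
  omega
}

# First/second derivatives of a T x k matrix of positions by central
# differences (one-sided at the ends), at sampling rate `rate`.
finite_difference <- function(x, rate, order = 1L) {
  x <- as.matrix(x)
  nt <- nrow(x)
  dt <- 1 / rate
  d <- matrix(NA_real_, nt, ncol(x))
  if (order == 1L) {
    d[2:(nt - 1L), ] <- (x[3:nt, , drop = FALSE] - x[1:(nt - 2L), , drop = FALSE]) / (2 * dt)
    d[1L, ] <- (x[2L, ] - x[1L, ]) / dt
    d[nt, ] <- (x[nt, ] - x[nt - 1L, ]) / dt
  } else if (order == 2L) {
    d[2:(nt - 1L), ] <- (x[3:nt, , drop = FALSE] - 2 * x[2:(nt - 1L), , drop = FALSE] +
                           x[1:(nt - 2L), , drop = FALSE]) / dt^2
    d[1L, ] <- d[2L, ]
    d[nt, ] <- d[nt - 1L, ]
  } else stop("order must be 1 or 2")
  d
}
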