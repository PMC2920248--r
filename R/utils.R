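## Small geometric helpers shared across modules.  All rotations are
## proper 3x3 matrices mapping body-frame vectors into the lab frame.

#' Rotation matrix from an axis and an angle
#'
#' Rodrigues' formula.  The axis need not be normalized; a zero axis (or a
#' zero angle) returns the identity.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle rotation angle in radians.
#' @return a 3x3 proper rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300 || angle == 0) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Re-orthonormalize a drifting rotation matrix (Gram-Schmidt on columns).
orthonormalize <- function(R) {
  e1 <- R[, 1] / sqrt(sum(R[, 1]^2))
  e2 <- R[, 2] - sum(R[, 2] * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

## Angle (degrees, in [0, 180]) between two vectors.
angle_between_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

## Uniform random unit vectors (n x 3 matrix).
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
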