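# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about the x-axis
#'
#' Rotation of a body-frame vector into the global frame for a body rolled by
#' `beta` about the (shared) x-axis. Positive roll lowers the moth's right
#' side in a +z-down global frame.
#'
#' @param beta_rad roll angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(beta_rad) {
  cb <- cos(beta_rad)
  sb <- sin(beta_rad)
  matrix(c(1, 0, 0,
           0, cb, sb,
           0, -sb, cb), nrow = 3)
  # column-major: columns are images of the body axes
}

# intrinsic z-y-x (yaw, pitch, roll) rotation: BRF -> GRF
rot_zyx <- function(yaw_rad, pitch_rad, roll_rad) {
  cy <- cos(yaw_rad); sy <- sin(yaw_rad)
  cp <- cos(pitch_rad); sp <- sin(pitch_rad)
  cr <- cos(roll_rad); sr <- sin(roll_rad)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), nrow = 3)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), nrow = 3)
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), nrow = 3)
  Rz %*% Ry %*% Rx
}

# decompose R (BRF -> GRF, intrinsic z-y-x) into yaw, pitch, roll (radians)
euler_zyx <- function(R) {
  pitch <- asin(-R[3, 1])
  if (abs(cos(pitch)) < 1e-12) {
    stop("gimbal degeneracy: pitch at +/-90 degrees")
  }
  yaw <- atan2(R[2, 1], R[1, 1])
  roll <- atan2(R[3, 2], R[3, 3])
  c(yaw = unname(yaw), pitch = unname(pitch), roll = unname(roll))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product for n x 3 matrices
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize a zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
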