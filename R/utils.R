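# Internal helpers: quaternion rotation, small numeric utilities.

#' @keywords internal
#' @noRd
quat_normalize <- function(q, tol = 1e-9, warn = TRUE) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion cannot be normalized")
  if (abs(n - 1) > tol) {
    if (warn) warning("non-unit quaternion normalized (|q| = ", format(n), ")")
    q <- q / n
  }
  q
}

# Rotation matrix from unit quaternion (w, x, y, z), right-handed.
#' @keywords internal
#' @noRd
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @keywords internal
#' @noRd
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

# Quaternion for a rotation of `angle` radians about the z axis.
#' @keywords internal
#' @noRd
quat_yaw <- function(angle) c(cos(angle / 2), 0, 0, sin(angle / 2))

# Quaternion for a rotation of `angle` radians about the y axis (pitch).
#' @keywords internal
#' @noRd
quat_pitch <- function(angle) c(cos(angle / 2), 0, sin(angle / 2), 0)

#' @keywords internal
#' @noRd
rot_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
}

#' @keywords internal
#' @noRd
stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a finite numeric scalar")
  invisible(x)
}

# Monotone (Hyman-filtered) cubic interpolator through knots; clamps outside.
#' @keywords internal
#' @noRd
mono_spline <- function(x, y) {
  f <- stats::splinefun(x, y, method = "hyman")
  lo <- min(x); hi <- max(x)
  function(t) f(pmin(pmax(t, lo), hi))
}

# Piecewise-linear interpolator, clamped outside the knot range.
#' @keywords internal
#' @noRd
lin_interp <- function(x, y) {
  function(t) stats::approx(x, y, xout = pmin(pmax(t, min(x)), max(x)))$y
}
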