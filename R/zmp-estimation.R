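# Sensor-side ZMP from the four foot-mounted force plates, and the
# foot-shape (insole outline) contact model.

#' Plate wrench
#'
#' Measurement of one foot-mounted force plate: its world position, force
#' and torque.
#'
#' @param position World position 3-vector (m).
#' @param force Force 3-vector (N).
#' @param torque Torque 3-vector (N m), default zero.
#' @param id Plate identifier, e.g. \code{"left_toe"}.
#' @return A list of class \code{plate_wrench}.
#' @export
plate_wrench <- function(position, force, torque = c(0, 0, 0), id = NA_character_) {
  if (length(position) != 3L || length(force) != 3L || length(torque) != 3L)
    stop("position, force and torque must be 3-vectors")
  if (!all(is.finite(c(position, force, torque)))) stop("wrench must be finite")
  structure(list(position = as.numeric(position), force = as.numeric(force),
                 torque = as.numeric(torque), id = id),
            class = "plate_wrench")
}

#' Measured ZMP from force-plate wrenches
#'
#' Moment-balance zero-moment point over 1-4 plates:
#' \deqn{x_{ZMP} = \frac{\sum_i \{-n_{iy} - (z_i - z_{zmp}) f_{ix} + x_i f_{iz}\}}
#'   {\sum_i f_{iz}}}
#' and symmetrically for the y axis. \code{form = "alternate"} replaces the
#' lever-arm term \code{x_i * f_iz} with \code{x_i * f_ix} (a variant kept
#' for comparison; the standard moment balance is the default).
#'
#' @param plates A list of [plate_wrench()] objects (1 to 4).
#' @param z_zmp Height of the ZMP plane (m), default 0 (ground).
#' @param force_threshold Minimum total vertical force (N); below it the
#'   sample is a flight phase and \code{NA} is returned (no ZMP exists).
#' @param form \code{"standard"} (default) or \code{"alternate"}.
#' @return Named numeric vector \code{c(x = , y = )} (m), or \code{NA}s in
#'   flight phase.
#' @export
measured_zmp <- function(plates, z_zmp = 0, force_threshold = 0,
                         form = c("standard", "alternate")) {
  form <- match.arg(form)
  if (inherits(plates, "plate_wrench")) plates <- list(plates)
  if (length(plates) < 1L || length(plates) > 4L)
    stop("between 1 and 4 plate wrenches expected")
  fz_sum <- sum(vapply(plates, function(p) p$force[3], 0))
  if (fz_sum <= force_threshold)
    return(c(x = NA_real_, y = NA_real_))
  num_x <- 0; num_y <- 0
  for (p in plates) {
    lever_x <- if (form == "standard") p$position[1] * p$force[3]
               else p$position[1] * p$force[1]
    num_x <- num_x + (-p$torque[2] - (p$position[3] - z_zmp) * p$force[1] + lever_x)
    num_y <- num_y + (p$torque[1] - (p$position[3] - z_zmp) * p$force[2] +
                        p$position[2] * p$force[3])
  }
  c(x = num_x / fz_sum, y = num_y / fz_sum)
}

#' Foot-shape (insole outline) model
#'
#' Insole outline points in the foot frame plus a rigid pose. The default
#' outline is a toe rectangle (0.090 x 0.080 m) and a heel rectangle
#' (0.080 x 0.080 m) matching the footprint of the toe- and heel-mounted
#' plates, discretized at 16 points on the sole plane.
#'
#' @param outline n x 2 matrix of insole coordinates (m) in the foot frame
#'   (x forward, y left), n >= 3; default the plate-footprint rectangles.
#' @param position Foot-frame origin in the world (m).
#' @param quaternion Unit quaternion \code{(w, x, y, z)}; normalized with a
#'   warning if its norm deviates by more than 1e-9.
#' @return A list of class \code{foot_shape_model}.
#' @export
foot_shape_model <- function(outline = default_insole_outline(),
                             position = c(0, 0, 0),
                             quaternion = c(1, 0, 0, 0)) {
  outline <- rbind(outline)
  if (ncol(outline) != 2L || nrow(outline) < 3L)
    stop("outline must be an n x 2 matrix with n >= 3")
  if (length(position) != 3L) stop("position must be a 3-vector")
  quaternion <- quat_normalize(quaternion)
  structure(list(outline = outline, position = as.numeric(position),
                 quaternion = quaternion),
            class = "foot_shape_model")
}

#' Default insole outline
#'
#' Sixteen points on the two plate-footprint rectangles: toe
#' 0.090 x 0.080 m spanning x in \code{[0.010, 0.100]}, heel
#' 0.080 x 0.080 m spanning x in \code{[-0.080, 0]}, both 0.080 m wide.
#'
#' @return 16 x 2 numeric matrix (m).
#' @export
default_insole_outline <- function() {
  rect <- function(x0, x1, y0, y1) {
    xs <- seq(x0, x1, length.out = 3)
    rbind(cbind(xs, y0), cbind(xs, y1), c((x0 + x1) / 2, (y0 + y1) / 2),
          c(x0, (y0 + y1) / 2))
  }
  out <- rbind(rect(0.010, 0.100, -0.040, 0.040),
               rect(-0.080, 0.000, -0.040, 0.040))
  unname(out)
}

#' Transform the foot outline to world coordinates
#'
#' Applies the rigid pose to the outline points (sole plane z = 0 in the
#' foot frame). Pairwise distances are preserved to 1e-9.
#'
#' @param model A [foot_shape_model()].
#' @return n x 3 matrix of world points (m).
#' @export
transform_foot_points <- function(model) {
  stopifnot(inherits(model, "foot_shape_model"))
  R <- quat_to_matrix(model$quaternion)
  pts <- cbind(model$outline, 0)
  t(R %*% t(pts)) + matrix(model$position, nrow(pts), 3, byrow = TRUE)
}

#' Foot clearance: lowest and highest outline point
#'
#' @param model A [foot_shape_model()].
#' @return Named numeric vector \code{c(min = , max = )}: minimum and
#'   maximum height (m) of the transformed outline points.
#' @export
foot_clearance <- function(model) {
  z <- transform_foot_points(model)[, 3]
  c(min = min(z), max = max(z))
}
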