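# 15-segment anthropometric body model: segment lengths, masses and
# center-of-mass ratios scaled from height and body mass.

# Reference segment table for a 1.65 m / 57.00 kg adult (lean build).
# length_m and mass_kg are the reference absolute values; gamma is the
# proximal-to-distal internal-division ratio locating the segment COM.
.segment_table <- function() {
  df <- data.frame(
    name = c("head", "chest", "body",
             "right_upper_arm", "right_fore_arm", "right_hand",
             "left_upper_arm", "left_fore_arm", "left_hand",
             "right_upper_leg", "right_lower_leg", "right_foot",
             "left_upper_leg", "left_lower_leg", "left_foot"),
    proximal = c("neck", "waist", "hip_center",
                 "right_shoulder", "right_elbow", "right_wrist",
                 "left_shoulder", "left_elbow", "left_wrist",
                 "right_hip", "right_knee", "right_ankle",
                 "left_hip", "left_knee", "left_ankle"),
    distal = c("head_top", "neck", "waist",
               "right_elbow", "right_wrist", "right_hand_tip",
               "left_elbow", "left_wrist", "left_hand_tip",
               "right_knee", "right_ankle", "right_toe",
               "left_knee", "left_ankle", "left_toe"),
    length_m = c(0.22, 0.45, 0.45,
                 0.25, 0.25, 0.17,
                 0.25, 0.25, 0.17,
                 0.33, 0.33, 0.10,
                 0.33, 0.33, 0.10),
    mass_kg = c(3.93, 17.21, 10.66,
                1.54, 0.91, 0.34,
                1.54, 0.91, 0.34,
                6.27, 2.91, 0.63,
                6.27, 2.91, 0.63),
    gc_ratio = c(0.821, 0.428, 0.609,
                 0.529, 0.415, 0.891,
                 0.529, 0.415, 0.891,
                 0.475, 0.406, 0.595,
                 0.475, 0.406, 0.595),
    stringsAsFactors = FALSE
  )
  df$length_fraction <- df$length_m / 1.65
  df$mass_fraction <- df$mass_kg / 57.00
  df
}

#' Build a 15-segment subject body model
#'
#' Scales a reference whole-body link model (head, upper and lower torso,
#' left/right upper arms, forearms, hands, thighs, shanks and feet) to a
#' subject's height and mass. Segment lengths scale with height, segment
#' masses with body mass; the per-segment center-of-mass ratio
#' (\code{gc_ratio}, the proximal-to-distal internal-division ratio) is
#' treated as population-constant.
#'
#' @param height Subject stature in metres (> 0).
#' @param mass Subject body mass in kilograms (> 0).
#' @return An object of class \code{subject_model}: a list with
#'   \code{height}, \code{mass} and a \code{segments} data frame holding,
#'   per segment, the proximal/distal joint names, absolute \code{length}
#'   (m), absolute \code{mass} (kg) and \code{gc_ratio}.
#' @examples
#' m <- build_subject_model(1.65, 57)
#' sum(m$segments$mass)  # equals 57
#' @export
build_subject_model <- function(height, mass) {
  stopifnot_scalar(height, "height"); stopifnot_scalar(mass, "mass")
  if (height <= 0) stop("`height` must be positive")
  if (mass <= 0) stop("`mass` must be positive")
  tab <- .segment_table()
  segments <- data.frame(
    name = tab$name, proximal = tab$proximal, distal = tab$distal,
    length = height * tab$length_fraction,
    mass = mass * tab$mass_fraction,
    gc_ratio = tab$gc_ratio,
    stringsAsFactors = FALSE
  )
  structure(
    list(height = height, mass = mass, segments = segments),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat("15-segment subject model\n")
  cat(sprintf("  height: %.3f m, mass: %.2f kg\n", x$height, x$mass))
  cat(sprintf("  segment mass sum: %.6f kg\n", sum(x$segments$mass)))
  invisible(x)
}

#' Segment center of mass from its joint endpoints
#'
#' The segment COM divides the proximal-to-distal joint vector internally at
#' ratio \code{gc_ratio}: \code{p_proximal + gc_ratio * (p_distal - p_proximal)}.
#'
#' @param p_proximal,p_distal Numeric 3-vectors (m), same frame.
#' @param gc_ratio Internal-division ratio in \code{[0, 1]}.
#' @return Numeric 3-vector (m).
#' @export
segment_com <- function(p_proximal, p_distal, gc_ratio) {
  if (length(p_proximal) != 3L || length(p_distal) != 3L)
    stop("joint positions must be 3-vectors")
  stopifnot_scalar(gc_ratio, "gc_ratio")
  if (gc_ratio < 0 || gc_ratio > 1) stop("`gc_ratio` must lie in [0, 1]")
  as.numeric(p_proximal) + gc_ratio * (as.numeric(p_distal) - as.numeric(p_proximal))
}

#' Whole-body center of mass
#'
#' Mass-weighted mean of the 15 segment COMs given the joint positions.
#'
#' @param model A \code{subject_model}.
#' @param joint_poses Named list (or 3-row matrix with column names) of joint
#'   positions in metres; every proximal and distal joint of the model must
#'   be present.
#' @return Numeric 3-vector (m).
#' @export
whole_body_com <- function(model, joint_poses) {
  stopifnot(inherits(model, "subject_model"))
  if (is.matrix(joint_poses))
    joint_poses <- stats::setNames(
      lapply(seq_len(ncol(joint_poses)), function(j) joint_poses[, j]),
      colnames(joint_poses))
  seg <- model$segments
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(seg))) {
    for (j in c(seg$proximal[i], seg$distal[i]))
      if (is.null(joint_poses[[j]]))
        stop("missing joint position: `", j, "`")
    ci <- segment_com(joint_poses[[seg$proximal[i]]],
                      joint_poses[[seg$distal[i]]], seg$gc_ratio[i])
    acc <- acc + seg$mass[i] * ci
  }
  acc / sum(seg$mass)
}
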