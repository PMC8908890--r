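# Trunk-fixed local coordinate frame for turning walks: per-sample frame at
# the waist's ground projection, X along the chest forward heading, Z up.

# chest yaw (heading) per sample, optionally low-pass filtered so step-cycle
# oscillation does not leak into the frame
#' @keywords internal
#' @noRd
.chest_yaw <- function(recording, filter = TRUE, cutoff_hz = 1) {
  qc <- paste0("chest_quat_", c("w", "x", "y", "z"))
  if (!all(qc %in% names(recording)))
    stop("missing chest orientation channels (chest_quat_w/x/y/z)")
  q <- as.matrix(recording[qc])
  n <- nrow(q)
  yaw <- numeric(n)
  for (i in seq_len(n)) {
    f <- quat_to_matrix(quat_normalize(q[i, ], warn = FALSE)) %*% c(1, 0, 0)
    yaw[i] <- atan2(f[2], f[1])
  }
  yaw <- .unwrap(yaw)
  if (filter && n > 30) {
    sr <- attr(recording, "sample_rate")
    bf <- signal::butter(2, min(cutoff_hz / (sr / 2), 0.99))
    yaw <- as.numeric(signal::filtfilt(bf, yaw))
  }
  yaw
}

#' @keywords internal
#' @noRd
.unwrap <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Transform a recording into the trunk-fixed local frame
#'
#' Per sample, positions are expressed relative to the waist's ground
#' projection with the X axis along the chest forward heading; vector
#' channels (velocities, forces, torques) are rotated into the same
#' orientation. The per-sample origin and yaw are stored in
#' \code{frame_origin_x/y} and \code{frame_yaw} so the transform is exactly
#' invertible, and \code{frame_path_s} accumulates the origin's
#' heading-projected path length, which restores a continuous forward axis
#' for identification (a turning walk becomes a straight one in
#' \code{com_x + frame_path_s}).
#'
#' @param recording A \code{gait_recording} in the global frame with waist
#'   position and chest orientation channels.
#' @param filter_yaw Low-pass filter the chest heading (2nd-order
#'   Butterworth) before building the frame; default \code{TRUE}.
#' @param cutoff_hz Filter cutoff (Hz), default 1.
#' @return A \code{gait_recording} with \code{frame = "local"}.
#' @export
to_local_frame <- function(recording, filter_yaw = TRUE, cutoff_hz = 1) {
  stopifnot(inherits(recording, "gait_recording"))
  if (identical(attr(recording, "frame"), "local"))
    stop("recording is already in the local frame")
  wc <- paste0("waist_pos_", c("x", "y"))
  if (!all(wc %in% names(recording)))
    stop("missing waist position channels (waist_pos_x/y)")
  yaw <- .chest_yaw(recording, filter = filter_yaw, cutoff_hz = cutoff_hz)
  ox <- recording$waist_pos_x; oy <- recording$waist_pos_y
  cy <- cos(yaw); sy <- sin(yaw)
  n <- nrow(recording)
  df <- as.data.frame(recording)

  to_loc_point <- function(x, y) {
    rx <- x - ox; ry <- y - oy
    list(x = cy * rx + sy * ry, y = -sy * rx + cy * ry)
  }
  to_loc_vec <- function(x, y) list(x = cy * x + sy * y, y = -sy * x + cy * y)

  pos_groups <- c("com", "waist_pos",
                  as.vector(outer(c("left", "right"),
                                  c("_foot_pos", "_ankle", "_knee",
                                    "_toe_pos", "_heel_pos"), paste0)))
  vec_groups <- c("dcom", as.vector(outer(c("left", "right"),
                                          c("_toe_f", "_heel_f",
                                            "_toe_n", "_heel_n"), paste0)))
  for (gp in pos_groups) {
    cx <- paste0(gp, "_x"); cyn <- paste0(gp, "_y")
    if (!all(c(cx, cyn) %in% names(df))) next
    p <- to_loc_point(df[[cx]], df[[cyn]])
    df[[cx]] <- p$x; df[[cyn]] <- p$y
  }
  for (gp in vec_groups) {
    cx <- paste0(gp, "_x"); cyn <- paste0(gp, "_y")
    if (!all(c(cx, cyn) %in% names(df))) next
    p <- to_loc_vec(df[[cx]], df[[cyn]])
    df[[cx]] <- p$x; df[[cyn]] <- p$y
  }
  for (gp in c("left_foot_quat", "right_foot_quat", "chest_quat")) {
    qc <- paste0(gp, "_", c("w", "x", "y", "z"))
    if (!all(qc %in% names(df))) next
    q <- as.matrix(df[qc])
    for (i in seq_len(n)) q[i, ] <- quat_multiply(quat_yaw(-yaw[i]), q[i, ])
    df[qc] <- q
  }

  # cumulative heading-projected path length of the frame origin
  s <- numeric(n)
  if (n > 1) {
    ym <- (yaw[-1] + yaw[-n]) / 2
    ds <- cos(ym) * diff(ox) + sin(ym) * diff(oy)
    s <- c(0, cumsum(ds))
  }
  df$frame_origin_x <- ox; df$frame_origin_y <- oy
  df$frame_yaw <- yaw; df$frame_path_s <- s
  gait_recording(df, frame = "local")
}

#' Invert the trunk-local transform
#'
#' Restores the global frame from the stored per-sample origin and yaw;
#' the round trip \code{from_local_frame(to_local_frame(x))} reproduces
#' \code{x} to 1e-9.
#'
#' @param recording A local-frame \code{gait_recording} carrying
#'   \code{frame_origin_x/y} and \code{frame_yaw}.
#' @return A global-frame \code{gait_recording}.
#' @export
from_local_frame <- function(recording) {
  stopifnot(inherits(recording, "gait_recording"))
  need <- c("frame_origin_x", "frame_origin_y", "frame_yaw")
  if (!all(need %in% names(recording)))
    stop("recording does not carry the stored local-frame columns")
  yaw <- recording$frame_yaw
  ox <- recording$frame_origin_x; oy <- recording$frame_origin_y
  cy <- cos(yaw); sy <- sin(yaw)
  df <- as.data.frame(recording)
  n <- nrow(df)

  to_glob_point <- function(x, y)
    list(x = ox + cy * x - sy * y, y = oy + sy * x + cy * y)
  to_glob_vec <- function(x, y) list(x = cy * x - sy * y, y = sy * x + cy * y)

  pos_groups <- c("com", "waist_pos",
                  as.vector(outer(c("left", "right"),
                                  c("_foot_pos", "_ankle", "_knee",
                                    "_toe_pos", "_heel_pos"), paste0)))
  vec_groups <- c("dcom", as.vector(outer(c("left", "right"),
                                          c("_toe_f", "_heel_f",
                                            "_toe_n", "_heel_n"), paste0)))
  for (gp in pos_groups) {
    cx <- paste0(gp, "_x"); cyn <- paste0(gp, "_y")
    if (!all(c(cx, cyn) %in% names(df))) next
    p <- to_glob_point(df[[cx]], df[[cyn]])
    df[[cx]] <- p$x; df[[cyn]] <- p$y
  }
  for (gp in vec_groups) {
    cx <- paste0(gp, "_x"); cyn <- paste0(gp, "_y")
    if (!all(c(cx, cyn) %in% names(df))) next
    p <- to_glob_vec(df[[cx]], df[[cyn]])
    df[[cx]] <- p$x; df[[cyn]] <- p$y
  }
  for (gp in c("left_foot_quat", "right_foot_quat", "chest_quat")) {
    qc <- paste0(gp, "_", c("w", "x", "y", "z"))
    if (!all(qc %in% names(df))) next
    q <- as.matrix(df[qc])
    for (i in seq_len(n)) q[i, ] <- quat_multiply(quat_yaw(yaw[i]), q[i, ])
    df[qc] <- q
  }
  df$frame_origin_x <- NULL; df$frame_origin_y <- NULL
  df$frame_yaw <- NULL; df$frame_path_s <- NULL
  gait_recording(df, frame = "global")
}
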