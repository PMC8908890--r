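# GaitRecording container and CSV I/O.
#
# Column dialect (one row per sample, SI units, header mandatory):
#   time_s
#   com_{x,y,z}, dcom_{x,y,z}
#   {left,right}_foot_pos_{x,y,z}, {left,right}_foot_quat_{w,x,y,z}
#   {left,right}_ankle_{x,y,z}, {left,right}_knee_{x,y,z}
#   waist_pos_{x,y,z}, chest_quat_{w,x,y,z}
#   {left,right}_{toe,heel}_pos_{x,y,z} / _f_{x,y,z} / _n_{x,y,z}
# Unknown columns are preserved.

MANDATORY_COLUMNS <- c(
  "time_s",
  paste0("com_", c("x", "y", "z")),
  paste0("dcom_", c("x", "y", "z"))
)

#' Construct a gait recording
#'
#' Wraps a per-sample data frame in the \code{gait_recording} class after
#' validating the mandatory columns and the time base.
#'
#' @param data Data frame with at least \code{time_s}, \code{com_x/y/z} and
#'   \code{dcom_x/y/z}.
#' @param frame Coordinate frame tag, \code{"global"} or \code{"local"}.
#' @return A \code{gait_recording} (data frame subclass with attributes
#'   \code{sample_rate} and \code{frame}).
#' @export
gait_recording <- function(data, frame = "global") {
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(data))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(data) == 0L) stop("empty recording")
  t <- data$time_s
  if (any(diff(t) <= 0)) stop("`time_s` must be strictly increasing")
  sr <- if (nrow(data) > 1L) 1 / stats::median(diff(t)) else NA_real_
  structure(data, class = c("gait_recording", "data.frame"),
            sample_rate = sr, frame = frame)
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("gait recording: %d samples at %.4g Hz (%.2f s), frame = %s, %d channels\n",
              nrow(x), attr(x, "sample_rate"),
              x$time_s[nrow(x)] - x$time_s[1], attr(x, "frame"), ncol(x)))
  invisible(x)
}

#' Read a gait recording from CSV
#'
#' @param path CSV file in the package recording dialect.
#' @param frame Frame tag to attach (default \code{"global"}, or
#'   \code{"local"} when the file carries \code{frame_yaw} columns).
#' @return A \code{gait_recording}.
#' @export
read_recording <- function(path, frame = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(frame))
    frame <- if ("frame_yaw" %in% names(df)) "local" else "global"
  gait_recording(df, frame = frame)
}

#' Write a gait recording to CSV
#'
#' Values round-trip through [read_recording()] to within 1e-12.
#'
#' @param recording A \code{gait_recording}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(recording)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) {
    # full binary precision so read.csv restores the doubles exactly
    as.numeric(formatC(col, digits = 17, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a recording to a uniform rate
#'
#' Linear interpolation of every numeric channel onto a uniform grid, e.g.
#' to convert 100 Hz captures to the 60 Hz analysis rate.
#'
#' @param recording A \code{gait_recording}.
#' @param rate Target sample rate (Hz).
#' @return A \code{gait_recording} at \code{rate}.
#' @export
resample_recording <- function(recording, rate = 60) {
  if (rate <= 0) stop("`rate` must be positive")
  t <- recording$time_s
  grid <- seq(t[1], t[length(t)], by = 1 / rate)
  out <- data.frame(time_s = grid)
  for (nm in setdiff(names(recording), "time_s")) {
    col <- recording[[nm]]
    out[[nm]] <- if (is.numeric(col)) stats::approx(t, col, xout = grid)$y
                 else col[findInterval(grid, t, all.inside = TRUE)]
  }
  gait_recording(out, frame = attr(recording, "frame"))
}

# Extract the four plate wrenches at sample i as plate_wrench objects.
#' @keywords internal
#' @noRd
plates_at_sample <- function(recording, i, feet = c("left", "right")) {
  out <- list()
  for (side in feet) for (part in c("toe", "heel")) {
    pre <- paste0(side, "_", part)
    pos_cols <- paste0(pre, "_pos_", c("x", "y", "z"))
    f_cols <- paste0(pre, "_f_", c("x", "y", "z"))
    n_cols <- paste0(pre, "_n_", c("x", "y", "z"))
    if (!all(c(pos_cols, f_cols) %in% names(recording))) next
    trq <- if (all(n_cols %in% names(recording)))
      as.numeric(recording[i, n_cols]) else c(0, 0, 0)
    out[[paste0(side, "_", part)]] <- plate_wrench(
      as.numeric(recording[i, pos_cols]),
      as.numeric(recording[i, f_cols]),
      trq, id = paste0(side, "_", part))
  }
  out
}

#' Sensor ZMP trace of a recording
#'
#' Applies [measured_zmp()] sample by sample over the four plate channels.
#'
#' @param recording A \code{gait_recording} with plate channels.
#' @param z_zmp ZMP plane height (m).
#' @param force_threshold Total vertical force (N) below which the sample
#'   is flagged as flight (\code{NA}).
#' @param form Moment-balance variant, see [measured_zmp()].
#' @return Data frame with \code{time_s}, \code{zmp_x}, \code{zmp_y}.
#' @export
recording_zmp <- function(recording, z_zmp = 0, force_threshold = 0,
                          form = c("standard", "alternate")) {
  form <- match.arg(form)
  pre <- as.vector(outer(c("left", "right"), c("toe", "heel"), paste, sep = "_"))
  fz_cols <- paste0(pre, "_f_z")
  if (!all(fz_cols %in% names(recording)))
    stop("recording lacks the four plate force channels")
  n <- nrow(recording)
  zx <- numeric(n); zy <- numeric(n)
  pos <- lapply(pre, function(p) as.matrix(recording[paste0(p, "_pos_", c("x", "y", "z"))]))
  frc <- lapply(pre, function(p) as.matrix(recording[paste0(p, "_f_", c("x", "y", "z"))]))
  trq <- lapply(pre, function(p) {
    cols <- paste0(p, "_n_", c("x", "y", "z"))
    if (all(cols %in% names(recording))) as.matrix(recording[cols])
    else matrix(0, n, 3)
  })
  fz_tot <- Reduce(`+`, lapply(frc, function(f) f[, 3]))
  num_x <- num_y <- numeric(n)
  for (k in seq_along(pre)) {
    lever_x <- if (form == "standard") pos[[k]][, 1] * frc[[k]][, 3]
               else pos[[k]][, 1] * frc[[k]][, 1]
    num_x <- num_x + (-trq[[k]][, 2] - (pos[[k]][, 3] - z_zmp) * frc[[k]][, 1] + lever_x)
    num_y <- num_y + (trq[[k]][, 1] - (pos[[k]][, 3] - z_zmp) * frc[[k]][, 2] +
                        pos[[k]][, 2] * frc[[k]][, 3])
  }
  flight <- fz_tot <= force_threshold
  zx <- ifelse(flight, NA_real_, num_x / fz_tot)
  zy <- ifelse(flight, NA_real_, num_y / fz_tot)
  data.frame(time_s = recording$time_s, zmp_x = zx, zmp_y = zy)
}
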