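# Capture-point model-predictive ZMP law for stepping, and its bilateral
# extension with left/right switching for continuous walking.

#' Stepping task
#'
#' One step of the capture-point MPC law: support-foot anchor, target
#' landing position and landing time.
#'
#' @param x_p Support-foot (axle) position (m).
#' @param x_sd Target stepping position (m).
#' @param T Landing time (s, absolute); may be \code{Inf} for a pure
#'   braking/stabilization task.
#' @param leg \code{"left"} or \code{"right"} (the swinging leg).
#' @return A list of class \code{stepping_task}.
#' @export
stepping_task <- function(x_p, x_sd, T, leg = c("right", "left")) {
  leg <- match.arg(leg)
  stopifnot_scalar(x_p, "x_p"); stopifnot_scalar(x_sd, "x_sd")
  if (!is.numeric(T) || length(T) != 1L || is.na(T)) stop("`T` must be numeric")
  structure(list(x_p = x_p, x_sd = x_sd, T = T, leg = leg),
            class = "stepping_task")
}

#' Capture-point model-predictive ZMP law
#'
#' Minimum-effort ZMP command that keeps the ZMP close to the support foot
#' while guaranteeing the capture point reaches the target stepping position
#' at the landing time:
#' \deqn{x_{ZMP}(t) = x_P + \frac{2\,(x_{CP} - e^{-\zeta_1 (T - t)} x_{SP})}
#'   {1 - e^{-2 \zeta_1 (T - t)}}}
#' with foot-relative capture point \eqn{x_{CP} = x + \dot x/\zeta_2 - x_P}
#' and target offset \eqn{x_{SP} = x_{Sd} - x_P}. The law is expressed
#' relative to the support foot and re-anchored by adding \code{x_p}. As
#' \code{T - t} grows the foot-relative command tends to \code{2 * x_cp}
#' (the pure braking law).
#'
#' @param state List with \code{x} (m), \code{xdot} (m/s).
#' @param task A \code{stepping_task} (or list with \code{x_p},
#'   \code{x_sd}, \code{T}).
#' @param t Current time (s), \code{t < task$T} expected; as \code{t}
#'   approaches \code{T} the remaining horizon is floored at
#'   \code{horizon_floor} so the command stays finite.
#' @param params A \code{pendulum_params}.
#' @param horizon_floor Minimum remaining horizon (s), default 1 ms.
#' @return Commanded ZMP (m).
#' @export
mpc_zmp <- function(state, task, t, params, horizon_floor = 1e-3) {
  s <- as_planar_state(state)
  z1 <- params$zeta1; z2 <- params$zeta2
  h <- max(task$T - t, horizon_floor)
  E <- if (is.finite(h)) exp(-z1 * h) else 0
  x_cp <- s$x + s$xdot / z2 - task$x_p
  x_sp <- task$x_sd - task$x_p
  task$x_p + 2 * (x_cp - E * x_sp) / (1 - E^2)
}

#' Option-B control schedule for bilateral walking
#'
#' Builds the table of control intervals used by [bilateral_mpc_zmp()]. Each
#' option-B window runs from one leg's toe-off to the opposite leg's
#' toe-off (spanning the double-support interval) and carries the swinging
#' leg's task; within a window the task anchor switches at the intervening
#' heel contact (support foot before, landed foot after).
#'
#' @param windows Data frame with one row per control interval and columns
#'   \code{leg}, \code{t_start}, \code{t_end}, \code{x_p}, \code{x_sd},
#'   \code{T_land}. \code{T_land} may be \code{Inf} for terminal braking.
#' @return An object of class \code{switch_schedule}.
#' @export
switch_schedule <- function(windows) {
  need <- c("leg", "t_start", "t_end", "x_p", "x_sd", "T_land")
  if (!all(need %in% names(windows)))
    stop("schedule needs columns: ", paste(need, collapse = ", "))
  windows <- windows[order(windows$t_start), , drop = FALSE]
  if (nrow(windows) > 1L) {
    gaps <- windows$t_start[-1] - windows$t_end[-nrow(windows)]
    if (any(abs(gaps) > 1e-9))
      stop("control intervals must tile time without gaps or overlaps")
  }
  if (any(windows$t_end <= windows$t_start))
    stop("interval end times must exceed start times")
  structure(windows, class = c("switch_schedule", "data.frame"))
}

#' Bilateral MPC ZMP with left/right switching
#'
#' Evaluates the capture-point MPC law with the task of the leg active at
#' time \code{t} under option-B switching (toe-off to opposite toe-off).
#'
#' @param state List with \code{x}, \code{xdot}.
#' @param schedule A [switch_schedule()].
#' @param t Current time (s); must be covered by the schedule.
#' @param params A \code{pendulum_params}.
#' @param horizon_floor Passed to [mpc_zmp()].
#' @return A list with \code{x_zmp} (m), \code{leg} (active-leg tag) and
#'   \code{interval} (row index of the schedule).
#' @export
bilateral_mpc_zmp <- function(state, schedule, t, params, horizon_floor = 1e-3) {
  i <- which(t >= schedule$t_start & t < schedule$t_end)
  if (length(i) == 0L) {
    # allow the final right endpoint
    if (abs(t - schedule$t_end[nrow(schedule)]) < 1e-12) i <- nrow(schedule)
    else stop(sprintf(
      "time %.4f s not covered by the control schedule [%.4f, %.4f]",
      t, schedule$t_start[1], schedule$t_end[nrow(schedule)]))
  }
  i <- i[1]
  task <- list(x_p = schedule$x_p[i], x_sd = schedule$x_sd[i],
               T = schedule$T_land[i])
  list(x_zmp = mpc_zmp(state, task, t, params, horizon_floor),
       leg = schedule$leg[i], interval = i)
}

#' Integrated squared ZMP deviation from the support foot
#'
#' Trapezoidal integral of \code{(x_zmp - x_p)^2} over a uniformly sampled
#' trace: the cost that the capture-point MPC law minimizes subject to the
#' terminal capture-point constraint.
#'
#' @param zmp_trace Numeric vector of ZMP samples (m) on a uniform grid.
#' @param x_p Support-foot position (m).
#' @param dt Sample spacing (s).
#' @return Objective value (m^2 s).
#' @export
zmp_objective <- function(zmp_trace, x_p, dt) {
  if (length(zmp_trace) == 0L) stop("empty ZMP trace")
  d2 <- (zmp_trace - x_p)^2
  if (length(d2) == 1L) return(d2 * dt)
  dt * (sum(d2) - (d2[1] + d2[length(d2)]) / 2)
}
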