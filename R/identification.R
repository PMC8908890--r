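# Identification of the balance-controller parameters from COM/ZMP time
# series, segmented at option-B windows (toe-off to opposite toe-off) and
# split at the intervening heel contact.

#' Segment a walking bout into identification windows
#'
#' Builds the fit windows from a phase timeline: each window runs from one
#' leg's toe-off to the opposite leg's toe-off and is split at the swinging
#' leg's heel contact into a pre- and a post-contact sub-segment. Toe-offs
#' that are not followed by an initial contact of the same leg (braking
#' transients at the walk stop) do not open windows.
#'
#' @param timelines A \code{phase_timelines} (from [detect_phases()] or a
#'   simulator's ground truth).
#' @param t_end End of the recording (s); defaults to the last timeline
#'   time. The final window (no opposite toe-off) extends to \code{t_end}.
#' @return Data frame with one row per window: \code{window}, \code{leg},
#'   \code{t_start}, \code{t_end}, \code{hc} (heel-contact time) and
#'   \code{T_next} (next heel contact of either leg, \code{Inf} at the
#'   terminal braking segment).
#' @export
segment_trials <- function(timelines, t_end = NULL) {
  ev <- timelines$events
  if (is.null(t_end)) {
    ends <- c(timelines$left$t_end, timelines$right$t_end, ev$time)
    t_end <- max(ends)
  }
  tos <- ev[ev$event == "psw_end", , drop = FALSE]
  tos <- tos[order(tos$time), , drop = FALSE]
  ics <- ev[ev$event == "IC", , drop = FALSE]
  ics <- ics[order(ics$time), , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(tos))) {
    leg <- tos$leg[i]; t0 <- tos$time[i]
    own_ic <- ics$time[ics$leg == leg & ics$time > t0 + 1e-9]
    if (length(own_ic) == 0L) next              # stop transient, no step follows
    hc <- own_ic[1]
    nxt <- which(tos$time > t0 + 1e-9)
    if (length(nxt) > 0L) {
      j <- nxt[1]
      if (tos$leg[j] == leg)
        stop(sprintf(
          "inconsistent event ordering: consecutive toe-offs of the %s leg at %.3f and %.3f s",
          leg, t0, tos$time[j]))
      t1 <- tos$time[j]
    } else t1 <- t_end
    if (hc >= t1) next
    later_ic <- ics$time[ics$time > hc + 1e-9]
    rows[[length(rows) + 1L]] <- data.frame(
      leg = leg, t_start = t0, t_end = t1, hc = hc,
      T_next = if (length(later_ic)) later_ic[1] else Inf,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(window = integer(), leg = character(),
                      t_start = numeric(), t_end = numeric(),
                      hc = numeric(), T_next = numeric()))
  out <- do.call(rbind, rows)
  out <- cbind(window = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# zero-phase low-pass around a linear trend (avoids filtfilt end
# transients on drifting signals)
#' @keywords internal
#' @noRd
.lowpass <- function(v, cutoff_hz, rate) {
  n <- length(v)
  if (is.null(cutoff_hz) || n < 30 || cutoff_hz >= rate / 2) return(v)
  slope <- (v[n] - v[1]) / (n - 1)
  base <- v[1] + slope * (seq_len(n) - 1)
  bf <- signal::butter(2, cutoff_hz / (rate / 2))
  base + as.numeric(signal::filtfilt(bf, v - base))
}

# Forward axis of a recording for identification: in the trunk-local frame
# the stored cumulative path offset restores a continuous inertial axis.
# COM position/velocity are low-pass filtered (standard 6 Hz kinematic
# smoothing) unless `lowpass_hz` is NULL.
#' @keywords internal
#' @noRd
.fit_axis <- function(recording, lowpass_hz = 6) {
  off <- if (identical(attr(recording, "frame"), "local") &&
             "frame_path_s" %in% names(recording))
    recording$frame_path_s else 0
  sr <- attr(recording, "sample_rate")
  list(
    t = recording$time_s,
    x = .lowpass(recording$com_x + off, lowpass_hz, sr),
    xdot = .lowpass(recording$dcom_x, lowpass_hz, sr),
    zmp = recording_zmp(recording)$zmp_x + off,
    foot_x = function(leg) recording[[paste0(leg, "_foot_pos_x")]] + off
  )
}

# Build the per-sub-segment design used by the fit: sample indices,
# terminal times and target stepping positions.
#' @keywords internal
#' @noRd
.fit_design <- function(recording, segments, trim = 1L, lowpass_hz = 6) {
  ax <- .fit_axis(recording, lowpass_hz)
  t <- ax$t
  subs <- list()
  for (i in seq_len(nrow(segments))) {
    w <- segments[i, ]
    hc_i <- which.min(abs(t - w$hc))
    x_sd_pre <- ax$foot_x(w$leg)[hc_i]
    opp <- if (w$leg == "left") "right" else "left"
    x_sd_post <- if (is.finite(w$T_next))
      ax$foot_x(opp)[which.min(abs(t - w$T_next))] else 0
    for (half in c("pre", "post")) {
      if (half == "pre") {
        sel <- which(t >= w$t_start - 1e-9 & t < w$hc - 1e-9)
        T_land <- w$hc; x_sd <- x_sd_pre
      } else {
        sel <- which(t >= w$hc - 1e-9 & t < w$t_end - 1e-9)
        T_land <- w$T_next; x_sd <- x_sd_post
      }
      if (trim > 0L && length(sel) > 2L * trim)
        sel <- sel[(trim + 1L):(length(sel) - trim)]
      ok <- sel[is.finite(ax$zmp[sel])]
      if (length(ok) < 3L) next
      subs[[length(subs) + 1L]] <- list(
        window = w$window, leg = w$leg, half = half, idx = ok,
        T_land = T_land, x_sd = x_sd,
        t = t[ok], xi0 = ax$x[ok], xdot = ax$xdot[ok], y = ax$zmp[ok])
    }
  }
  if (length(subs) == 0L) stop("no usable identification segments")
  subs
}

# Sum of squares at (zeta1, zeta2) with the per-segment anchor solved in
# closed form (the model is affine in x_p).
#' @keywords internal
#' @noRd
.fit_sse <- function(z1, z2, subs, horizon_floor = 1e-3) {
  sse <- 0; n <- 0; xp <- numeric(length(subs))
  for (k in seq_along(subs)) {
    s <- subs[[k]]
    xi <- s$xi0 + s$xdot / z2
    E <- if (is.finite(s$T_land))
      exp(-z1 * pmax(s$T_land - s$t, horizon_floor)) else rep(0, length(s$t))
    alpha <- (E - 1) / (1 + E)
    beta <- 2 * (xi - E * s$x_sd) / (1 - E^2)
    denom <- sum(alpha^2)
    xp_k <- if (denom > 1e-12) sum(alpha * (s$y - beta)) / denom else 0
    r <- s$y - alpha * xp_k - beta
    sse <- sse + sum(r^2); n <- n + length(r); xp[k] <- xp_k
  }
  list(sse = sse, n = n, xp = xp)
}

#' Fit the walking balance controller to a recording
#'
#' Identifies the COM-ZMP controller eigenvalues (and the per-segment
#' support anchors) by least squares between the capture-point MPC model
#' ZMP, evaluated along the measured COM trajectory, and the sensor ZMP
#' estimated from the force plates. The fit windows run from toe-off to
#' opposite toe-off and are split at the heel contact; the target stepping
#' positions and event times are taken from the phase timeline, not
#' co-estimated. Optionally the eigenvalue product is constrained
#' (\code{zeta1 * zeta2 = constraint_product}), in which case only
#' \code{zeta1} is free. Optimization is bounded multi-start
#' quasi-Newton with a fixed seed, so results are reproducible.
#'
#' @param recording A \code{gait_recording} (global or trunk-local frame).
#' @param timelines A \code{phase_timelines}; if \code{NULL}, phases are
#'   detected with default thresholds.
#' @param segments Fit windows from [segment_trials()]; computed from
#'   \code{timelines} when \code{NULL}.
#' @param constraint_product Optional eigenvalue product (1/s^2), e.g.
#'   8.67; \code{NULL} fits both eigenvalues freely.
#' @param zeta_bounds Search bounds for the eigenvalues (1/s).
#' @param n_starts Number of multi-start initial points (default 8).
#' @param seed RNG seed for the multi-start draws.
#' @param trim Samples dropped at each sub-segment boundary (default 1;
#'   detected heel contacts land on the sample after the true event).
#' @param horizon_floor Remaining-horizon floor of the MPC law (s).
#' @param lowpass_hz Zero-phase low-pass cutoff (Hz) applied to the COM
#'   position and velocity channels before fitting, the standard kinematic
#'   smoothing for gait data; \code{NULL} disables it.
#' @param subject Optional \code{subject_model} passed to the detector.
#' @return An object of class \code{balance_fit} with components
#'   \code{zeta1}, \code{zeta2}, \code{x_p} (per sub-segment anchors),
#'   \code{rmse} (m), \code{constraint_product}, \code{segments},
#'   \code{converged}, and the training data needed by the methods
#'   (\code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict}, \code{plot}, \code{simulate}).
#' @examples
#' sim <- simulate_walk(walk_scenario(n_steps = 4, noise = NULL))
#' fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
#'                               constraint_product = 8.64)
#' coef(fit)
#' @export
fit_balance_controller <- function(recording, timelines = NULL,
                                   segments = NULL,
                                   constraint_product = NULL,
                                   zeta_bounds = c(1, 10),
                                   n_starts = 8L, seed = 0L, trim = 1L,
                                   horizon_floor = 1e-3, lowpass_hz = 6,
                                   subject = NULL) {
  stopifnot(inherits(recording, "gait_recording"))
  if (is.null(segments)) {
    if (is.null(timelines))
      timelines <- detect_phases(recording, model = subject)
    segments <- segment_trials(timelines,
                               t_end = recording$time_s[nrow(recording)])
  }
  if (nrow(segments) == 0L) stop("no identification windows in the timeline")
  subs <- .fit_design(recording, segments, trim = trim, lowpass_hz = lowpass_hz)

  obj <- if (is.null(constraint_product)) {
    function(par) .fit_sse(par[1], par[2], subs, horizon_floor)$sse
  } else {
    function(par) .fit_sse(par[1], constraint_product / par[1], subs,
                           horizon_floor)$sse
  }
  npar <- if (is.null(constraint_product)) 2L else 1L
  lower <- rep(zeta_bounds[1], npar); upper <- rep(zeta_bounds[2], npar)

  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * npar, zeta_bounds[1], zeta_bounds[2]),
                   ncol = npar)
  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimizer failed from every start")

  z1 <- best$par[1]
  z2 <- if (is.null(constraint_product)) best$par[2] else constraint_product / z1
  final <- .fit_sse(z1, z2, subs, horizon_floor)
  rmse <- sqrt(final$sse / final$n)

  seg_out <- do.call(rbind, lapply(seq_along(subs), function(k) data.frame(
    window = subs[[k]]$window, leg = subs[[k]]$leg, half = subs[[k]]$half,
    t_start = subs[[k]]$t[1], t_end = subs[[k]]$t[length(subs[[k]]$t)],
    T_land = subs[[k]]$T_land, x_sd = subs[[k]]$x_sd, x_p = final$xp[k],
    n = length(subs[[k]]$idx), stringsAsFactors = FALSE)))

  structure(list(
    zeta1 = z1, zeta2 = z2, x_p = final$xp,
    x_sd = vapply(subs, function(s) s$x_sd, 0),
    rmse = rmse, constraint_product = constraint_product,
    segments = seg_out, windows = segments,
    converged = best$convergence == 0 || final$sse <= final$n * 1e-12,
    n_obs = final$n, seed = seed, n_starts = n_starts,
    zeta_bounds = zeta_bounds, horizon_floor = horizon_floor,
    lowpass_hz = lowpass_hz,
    frame = attr(recording, "frame"),
    subs = subs
  ), class = "balance_fit")
}

# model ZMP over the stored (or freshly built) sub-segments at the fitted
# parameters, with the anchors re-solved when new data is supplied
#' @keywords internal
#' @noRd
.eval_model <- function(fit, subs, xp = NULL) {
  z1 <- fit$zeta1; z2 <- fit$zeta2; hf <- fit$horizon_floor
  if (is.null(xp)) xp <- .fit_sse(z1, z2, subs, hf)$xp
  out <- lapply(seq_along(subs), function(k) {
    s <- subs[[k]]
    xi <- s$xi0 + s$xdot / z2
    E <- if (is.finite(s$T_land))
      exp(-z1 * pmax(s$T_land - s$t, hf)) else rep(0, length(s$t))
    alpha <- (E - 1) / (1 + E)
    beta <- 2 * (xi - E * s$x_sd) / (1 - E^2)
    data.frame(time_s = s$t, window = s$window, leg = s$leg, half = s$half,
               model_zmp_x = alpha * xp[k] + beta, measured_zmp_x = s$y,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$time_s), , drop = FALSE]
}

#' Model ZMP trace of a fitted balance controller
#'
#' Evaluates the fitted MPC law along the measured COM trajectory over the
#' identification windows, producing the continuous model-vs-sensor ZMP
#' comparison trace.
#'
#' @param fit A \code{balance_fit}.
#' @param recording,timelines Optional new data; defaults to the training
#'   segments (where the reported RMSE equals \code{fit$rmse}).
#' @return Data frame with \code{time_s}, \code{model_zmp_x},
#'   \code{measured_zmp_x}, window and sub-segment tags; attribute
#'   \code{rmse}.
#' @export
model_zmp_trace <- function(fit, recording = NULL, timelines = NULL) {
  stopifnot(inherits(fit, "balance_fit"))
  if (is.null(recording)) {
    tr <- .eval_model(fit, fit$subs, xp = fit$x_p)
  } else {
    if (is.null(timelines)) timelines <- detect_phases(recording)
    segments <- segment_trials(timelines,
                               t_end = recording$time_s[nrow(recording)])
    subs <- .fit_design(recording, segments, trim = 0L,
                        lowpass_hz = fit$lowpass_hz)
    tr <- .eval_model(fit, subs)
  }
  attr(tr, "rmse") <- sqrt(mean((tr$model_zmp_x - tr$measured_zmp_x)^2))
  tr
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.balance_fit <- function(x, ...) {
  cat("COM-ZMP balance-controller fit\n")
  cat(sprintf("  zeta1 = %.4f 1/s, zeta2 = %.4f 1/s%s\n", x$zeta1, x$zeta2,
              if (!is.null(x$constraint_product))
                sprintf(" (product constrained to %.3g 1/s^2)",
                        x$constraint_product) else ""))
  cat(sprintf("  %d sub-segments, %d samples, rmse = %.4g m, frame = %s\n",
              nrow(x$segments), x$n_obs, x$rmse, x$frame))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.balance_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.balance_fit")
}

#' @export
print.summary.balance_fit <- function(x, ...) {
  print(x$fit)
  cat("\nper-segment support anchors:\n")
  print(x$fit$segments, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.balance_fit <- function(object, ...) {
  c(zeta1 = object$zeta1, zeta2 = object$zeta2)
}

#' @export
fitted.balance_fit <- function(object, ...) {
  .eval_model(object, object$subs, xp = object$x_p)$model_zmp_x
}

#' @export
residuals.balance_fit <- function(object, ...) {
  tr <- .eval_model(object, object$subs, xp = object$x_p)
  tr$measured_zmp_x - tr$model_zmp_x
}

#' @export
predict.balance_fit <- function(object, recording = NULL, timelines = NULL, ...) {
  model_zmp_trace(object, recording = recording, timelines = timelines)
}

#' @export
plot.balance_fit <- function(x, ...) {
  tr <- .eval_model(x, x$subs, xp = x$x_p)
  graphics::plot(tr$time_s, tr$measured_zmp_x, type = "l", col = "red",
                 xlab = "time [s]", ylab = "ZMP [m]",
                 main = "sensor ZMP (red) vs model ZMP (blue)", ...)
  graphics::lines(tr$time_s, tr$model_zmp_x, col = "blue")
  invisible(x)
}

#' @export
simulate.balance_fit <- function(object, nsim = 1, seed = NULL, ...,
                                 scenario = NULL) {
  if (is.null(scenario))
    scenario <- walk_scenario(zeta1 = object$zeta1, zeta2 = object$zeta2,
                              noise = NULL)
  else {
    scenario$params <- pendulum_params(object$zeta1, object$zeta2,
                                       g = scenario$params$g)
  }
  sims <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    if (!is.null(seed)) scenario$seed <- as.integer(seed) + i - 1L
    sims[[i]] <- simulate_walk(scenario)
  }
  if (nsim == 1L) sims[[1L]] else sims
}
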