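# Closed-loop inverted-pendulum walker and sensor-signal synthesizer.
# Produces 60 Hz gait recordings with ground-truth phases so the detector,
# the ZMP estimator and the identification can be tested without hardware.

#' Walk scenario
#'
#' Study conditions for the synthetic walker: step geometry and timing,
#' controller eigenvalues, subject, noise model and seed.
#'
#' @param kind \code{"stepping"} (single step and braking),
#'   \code{"straight_walk"} or \code{"turn_walk"}.
#' @param n_steps Number of steps (forced to 1 for stepping).
#' @param stride Step length (m); nominal range 0.1-0.6.
#' @param step_duration Time between successive heel contacts (s); the gait
#'   cycle is twice this.
#' @param turn_angle Heading change (degrees) for turn walks, default 90.
#' @param turn_step Step at which the turn is centered; default the middle
#'   step.
#' @param subject A \code{subject_model}; default 1.65 m / 57 kg.
#' @param zeta1,zeta2 Controller eigenvalue magnitudes (1/s); defaults are
#'   the identified values 4 and 2.16 (product 8.64, i.e. the 8.67
#'   constraint satisfied to rounding).
#' @param g Gravitational acceleration (m/s^2).
#' @param z_com Constant COM height (m); default \code{g/(zeta1*zeta2)} so
#'   the equivalent symmetric pendulum matches the eigenvalue product.
#' @param noise Per-channel Gaussian noise standard deviations:
#'   list(pos, vel, force, torque) in m, m/s, N, N m. \code{NULL} for a
#'   noiseless recording. Default 2 mm, 10 mm/s, 2 N, 0.05 N m.
#' @param seed RNG seed for the noise draws.
#' @param sample_rate Recording rate (Hz), default 60.
#' @param swing_frac Per-leg swing fraction of the gait cycle,
#'   \code{c(left=, right=)}; default 0.38 both sides (the 62/38
#'   stance/swing split of normal gait).
#' @param lead_in Standing time before the first step (s).
#' @param brake_duration Recording time after the last heel contact (s).
#' @param first_leg Leg of the first step.
#' @param max_zmp_offset Feasibility bound: largest admissible distance (m)
#'   between the commanded ZMP and the support anchor before the stepping
#'   task is declared infeasible.
#' @return A list of class \code{walk_scenario}.
#' @export
walk_scenario <- function(kind = c("straight_walk", "stepping", "turn_walk"),
                          n_steps = 6, stride = 0.3, step_duration = 0.6,
                          turn_angle = 90, turn_step = NULL,
                          subject = build_subject_model(1.65, 57),
                          zeta1 = 4, zeta2 = 2.16, g = 9.81,
                          z_com = g / (zeta1 * zeta2),
                          noise = list(pos = 0.002, vel = 0.010,
                                       force = 2, torque = 0.05),
                          seed = 1L, sample_rate = 60,
                          swing_frac = c(left = 0.38, right = 0.38),
                          lead_in = 0.5, brake_duration = 1.2,
                          first_leg = "right", max_zmp_offset = 0.5) {
  kind <- match.arg(kind)
  if (kind == "stepping") n_steps <- 1L
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  if (stride < 0.05 || stride > 1)
    stop("`stride` outside the supported range")
  if (is.null(turn_step)) turn_step <- ceiling((n_steps + 1) / 2)
  if (length(swing_frac) == 1L) swing_frac <- c(left = swing_frac, right = swing_frac)
  if (any(swing_frac < 0.3 | swing_frac > 0.48))
    stop("`swing_frac` must lie in [0.30, 0.48]")
  structure(list(
    kind = kind, n_steps = as.integer(n_steps), stride = stride,
    step_duration = step_duration, turn_angle = turn_angle,
    turn_step = turn_step, subject = subject,
    params = pendulum_params(zeta1, zeta2, g = g, z_com = z_com),
    noise = noise, seed = as.integer(seed), sample_rate = sample_rate,
    swing_frac = swing_frac, lead_in = lead_in,
    brake_duration = brake_duration, first_leg = first_leg,
    max_zmp_offset = max_zmp_offset
  ), class = "walk_scenario")
}

# --- schedule -------------------------------------------------------------

# Step schedule: heel contacts, toe-offs, landings and control intervals.
#' @keywords internal
#' @noRd
.walk_schedule <- function(sc) {
  n <- sc$n_steps
  cyc <- 2 * sc$step_duration
  legs <- rep(c(sc$first_leg, setdiff(c("left", "right"), sc$first_leg)),
              length.out = n)
  swing_dur <- sc$swing_frac[legs] * cyc
  hc <- sc$lead_in + seq_len(n) * sc$step_duration
  to <- hc - swing_dur
  land_x <- seq_len(n) * sc$stride
  foot_y <- c(left = 0.09, right = -0.09)
  t_end <- hc[n] + sc$brake_duration

  # control intervals: task anchors switch at heel contacts; the first
  # interval spans the standing lead-in, the last is terminal braking
  k <- seq_len(n)
  x_sup <- c(0, land_x)[k]            # support foot at step k
  ivals <- data.frame(
    leg = legs,
    t_start = c(0, hc[-n]), t_end = hc,
    x_p = x_sup, x_sd = land_x, T_land = hc,
    stringsAsFactors = FALSE)
  ivals <- rbind(ivals, data.frame(
    leg = legs[n], t_start = hc[n], t_end = t_end,
    x_p = land_x[n], x_sd = land_x[n], T_land = Inf))

  list(n = n, cycle = cyc, legs = legs, hc = hc, to = to,
       land_x = land_x, foot_y = foot_y, t_end = t_end,
       swing_dur = swing_dur, stance_dur = cyc - swing_dur,
       intervals = switch_schedule(ivals))
}

# --- closed-loop integration ---------------------------------------------

#' @keywords internal
#' @noRd
.integrate_walk <- function(sc, sched, n_sub = 10L) {
  p <- sc$params
  dt_s <- 1 / sc$sample_rate
  times <- seq(0, sched$t_end, by = dt_s)
  nt <- length(times)
  x <- numeric(nt); v <- numeric(nt); zmp <- numeric(nt); leg <- character(nt)
  s <- c(0, 0)
  h <- dt_s / n_sub
  for (i in seq_len(nt)) {
    out <- bilateral_mpc_zmp(list(x = s[1], xdot = s[2]), sched$intervals,
                             times[i], p)
    x[i] <- s[1]; v[i] <- s[2]; zmp[i] <- out$x_zmp; leg[i] <- out$leg
    if (abs(out$x_zmp - sched$intervals$x_p[out$interval]) > sc$max_zmp_offset) {
      step_no <- min(out$interval, sched$n)
      stop(sprintf(
        "infeasible stepping task at step %d: commanded ZMP %.3f m from the support anchor",
        step_no, abs(out$x_zmp - sched$intervals$x_p[out$interval])))
    }
    if (i == nt) break
    for (j in seq_len(n_sub)) {
      t0 <- times[i] + (j - 1) * h
      f <- function(t, st) {
        zm <- bilateral_mpc_zmp(list(x = st[1], xdot = st[2]),
                                sched$intervals, min(t, sched$t_end), p)$x_zmp
        c(st[2], p$zeta1 * p$zeta2 * (st[1] - zm) +
            (p$zeta1 - p$zeta2) * st[2])
      }
      k1 <- f(t0, s); k2 <- f(t0 + h / 2, s + h / 2 * k1)
      k3 <- f(t0 + h / 2, s + h / 2 * k2); k4 <- f(t0 + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  data.frame(time_s = times, x = x, v = v, true_zmp_x = zmp,
             active_leg = leg, stringsAsFactors = FALSE)
}

# --- ground-truth phase timeline ------------------------------------------

# Per-leg episode plan: stance/swing spans with the knot times every
# synthesizer (and the truth timeline) shares.
#' @keywords internal
#' @noRd
.leg_plan <- function(sc, sched, leg) {
  n <- sched$n; cyc <- sched$cycle
  ks <- which(sched$legs == leg)            # steps this leg swings
  sw <- sc$swing_frac[[leg]] * cyc
  st <- cyc - sw
  u_lr <- 0.10 / 0.62; u_mst <- 0.30 / 0.62  # stance-normalized boundaries
  episodes <- list()
  add <- function(e) episodes[[length(episodes) + 1L]] <<- e

  if (length(ks) > 0L) {
    k1 <- ks[1]
    if (k1 == 1L) {
      add(list(type = "initial", t0 = 0, t1 = sched$to[1], x = 0,
               mst_end = sched$to[1] - 0.1, tst_end = sched$to[1]))
    } else {
      add(list(type = "initial", t0 = 0, t1 = sched$to[k1], x = 0,
               mst_end = sched$hc[k1 - 1L] - 0.2 * cyc,
               tst_end = sched$hc[k1 - 1L]))
    }
    for (k in ks) {
      x_prev <- if (k <= 2L) 0 else sched$land_x[k - 2L]
      x_sup <- if (k == 1L) 0 else sched$land_x[k - 1L]
      sdur <- sched$hc[k] - sched$to[k]
      s_c <- if (abs(x_sup - x_prev) < 1e-12) 0 else 13 / 38
      add(list(type = "swing", t0 = sched$to[k], t1 = sched$hc[k],
               x0 = x_prev, x1 = sched$land_x[k], x_sup = x_sup,
               isw_end = sched$to[k] + s_c * sdur,
               msw_end = sched$hc[k] - (12 / 38) * sdur))
      if ((k + 2L) %in% ks) {
        add(list(type = "steady", t0 = sched$hc[k], t1 = sched$to[k + 2L],
                 x = sched$land_x[k], stance = sched$to[k + 2L] - sched$hc[k],
                 lr_end = sched$hc[k] + u_lr * st,
                 mst_end = sched$hc[k] + u_mst * st,
                 tst_end = sched$hc[k + 1L]))
      } else if (k == n) {
        add(list(type = "final_lead", t0 = sched$hc[n], t1 = sched$t_end,
                 x = sched$land_x[n], lr_end = sched$hc[n] + u_lr * st))
      } else {  # k == n - 1: trailing foot of the stop
        add(list(type = "final_trailing", t0 = sched$hc[k], t1 = sched$t_end,
                 x = sched$land_x[k], stance = st,
                 lr_end = sched$hc[k] + u_lr * st,
                 mst_end = sched$hc[k] + u_mst * st,
                 tst_end = sched$hc[n],
                 psw_end = sched$hc[n] + 0.25 * cyc))
      }
    }
  } else {
    # stepping-support leg: planted throughout, unloads after the step
    add(list(type = "support_only", t0 = 0, t1 = sched$t_end, x = 0,
             unload = sched$hc[n] + 0.3))
  }
  list(leg = leg, episodes = episodes, stance_dur = st, swing_dur = sw)
}

#' @keywords internal
#' @noRd
.truth_timeline <- function(plans, t_end) {
  tl_all <- list(); ev_all <- list()
  for (plan in plans) {
    leg <- plan$leg
    seg <- list(); ev <- list()
    phase <- function(p, a, b) seg[[length(seg) + 1L]] <<- data.frame(
      leg = leg, phase = p, t_start = a, t_end = b, stringsAsFactors = FALSE)
    event <- function(e, t) ev[[length(ev) + 1L]] <<- data.frame(
      leg = leg, event = e, time = t, stringsAsFactors = FALSE)
    for (e in plan$episodes) {
      if (e$type == "initial") {
        phase("MidStance", e$t0, e$mst_end); event("mst_end", e$mst_end)
        phase("TerminalStance", e$mst_end, e$tst_end); event("tst_end", e$tst_end)
        phase("PreSwing", e$tst_end, e$t1); event("psw_end", e$t1)
      } else if (e$type == "swing") {
        phase("InitialSwing", e$t0, e$isw_end); event("isw_end", e$isw_end)
        phase("MidSwing", e$isw_end, e$msw_end); event("msw_end", e$msw_end)
        phase("TerminalSwing", e$msw_end, e$t1); event("IC", e$t1)
      } else if (e$type == "steady") {
        phase("LoadingResponse", e$t0, e$lr_end); event("lr_end", e$lr_end)
        phase("MidStance", e$lr_end, e$mst_end); event("mst_end", e$mst_end)
        phase("TerminalStance", e$mst_end, e$tst_end); event("tst_end", e$tst_end)
        phase("PreSwing", e$tst_end, e$t1); event("psw_end", e$t1)
      } else if (e$type == "final_lead") {
        phase("LoadingResponse", e$t0, e$lr_end); event("lr_end", e$lr_end)
        phase("MidStance", e$lr_end, e$t1)
      } else if (e$type == "final_trailing") {
        phase("LoadingResponse", e$t0, e$lr_end); event("lr_end", e$lr_end)
        phase("MidStance", e$lr_end, e$mst_end); event("mst_end", e$mst_end)
        phase("TerminalStance", e$mst_end, e$tst_end); event("tst_end", e$tst_end)
        phase("PreSwing", e$tst_end, e$psw_end); event("psw_end", e$psw_end)
        phase("InitialSwing", e$psw_end, e$t1)
      } else if (e$type == "support_only") {
        phase("MidStance", e$t0, e$unload)
        phase("TerminalStance", e$unload, e$unload)
        phase("PreSwing", e$unload, e$unload)
        phase("InitialSwing", e$unload, e$t1)
      }
    }
    tl_all[[leg]] <- structure(do.call(rbind, seg),
                               class = c("phase_timeline", "data.frame"))
    ev_all[[leg]] <- do.call(rbind, ev)
  }
  structure(list(left = tl_all$left, right = tl_all$right,
                 events = do.call(rbind, ev_all),
                 thresholds = NULL, diagnostics = NULL),
            class = "phase_timelines")
}

# --- foot kinematics -------------------------------------------------------

# local foot geometry shared with the plate synthesizer
FOOT_TOE_X <- 0.10; FOOT_HEEL_X <- -0.08
PLATE_TOE <- c(0.055, 0, 0.005); PLATE_HEEL <- c(-0.040, 0, 0.005)
ANKLE_OFFSET <- c(-0.02, 0, 0.08)
PITCH_IC <- -0.17   # heel-down strike attitude (rad)
PITCH_TO <- 0.35    # heel-rise attitude at toe-off (rad)

# foot-origin height that puts the lowest outline point at z_low
#' @keywords internal
#' @noRd
.pivot_z <- function(pitch, z_low = 0) {
  lowest <- pmin(-sin(pitch) * FOOT_TOE_X, -sin(pitch) * FOOT_HEEL_X)
  z_low - lowest
}

#' Synthesize foot, ankle and knee kinematics
#'
#' Builds foot pose (position + pitch quaternion), ankle and knee channels
#' that satisfy every kinematic phase rule at the ground-truth event times:
#' heel-pivot pitch during loading response, flat foot in mid-stance, heel
#' rise in terminal stance, swing clearance, ankle crossing at the initial
#' to mid-swing boundary and a vertical shank at the mid to terminal swing
#' boundary.
#'
#' @param sim A \code{gait_simulation} (or the internal core built by
#'   [simulate_walk()]).
#' @param subject A \code{subject_model} (shank length scales the knee
#'   channel).
#' @return Data frame of per-sample foot/ankle/knee channels.
#' @export
synthesize_foot_kinematics <- function(sim, subject = sim$scenario$subject) {
  sched <- sim$schedule_internal; sc <- sim$scenario
  times <- sim$states$time_s
  shank <- subject$segments$length[subject$segments$name == "right_lower_leg"]
  out <- data.frame(time_s = times)

  for (plan in sim$plans) {
    leg <- plan$leg
    y <- sched$foot_y[[leg]]
    n <- length(times)
    fx <- numeric(n); pitch <- numeric(n); zlow <- numeric(n); phi <- rep(0.05, n)

    for (e in plan$episodes) {
      idx <- which(times >= e$t0 - 1e-9 & times <= e$t1 + 1e-9)
      if (length(idx) == 0L) next
      tt <- times[idx]
      if (e$type %in% c("initial", "support_only")) {
        fx[idx] <- e$x
        if (e$type == "initial" && !is.null(e$mst_end)) {
          # heel rise toward toe-off
          ramp <- lin_interp(c(e$t0, e$mst_end, e$t1), c(0, 0, PITCH_TO))
          pitch[idx] <- ramp(tt)
        } else pitch[idx] <- 0
        zlow[idx] <- 0
      } else if (e$type == "swing") {
        s <- (tt - e$t0) / (e$t1 - e$t0)
        dx <- e$x1 - e$x0
        s_c <- (e$isw_end - e$t0) / (e$t1 - e$t0)
        kn_s <- if (s_c > 0.05)
          c(0, s_c, 0.9, 1) else c(0, 0.9, 1)
        kn_v <- if (s_c > 0.05)
          c(0, (e$x_sup - e$x0) / max(dx, 1e-9), 0.98, 1) else c(0, 0.98, 1)
        prof <- mono_spline(kn_s, kn_v)
        fx[idx] <- e$x0 + dx * prof(s)
        pitch[idx] <- lin_interp(c(0, 0.5, 0.8, 1),
                                 c(PITCH_TO, -0.05, PITCH_IC, PITCH_IC))(s)
        zlow[idx] <- 0.06 * sin(pi * pmin(pmax(s, 0), 1))
        s_m <- (e$msw_end - e$t0) / (e$t1 - e$t0)
        phi[idx] <- lin_interp(c(0, s_m - 0.08, s_m, s_m + 0.06, 1),
                               c(0.60, 0.35, 0, -0.05, -0.05))(s)
      } else if (e$type == "steady" || e$type == "final_trailing") {
        fx[idx] <- e$x
        st <- e$stance
        u <- (tt - e$t0) / st
        pk <- lin_interp(c(0, 0.10 / 0.62, 0.30 / 0.62, 0.34 / 0.62, 1),
                         c(PITCH_IC, 0, 0, 0.15, PITCH_TO))
        pitch[idx] <- pk(u)
        if (e$type == "final_trailing") {
          # settle flat again during the stop
          settle <- which(tt > e$tst_end)
          if (length(settle)) {
            p_at <- pk((e$tst_end - e$t0) / st)
            pitch[idx[settle]] <- lin_interp(
              c(e$tst_end, e$psw_end, e$t1), c(p_at, 0, 0))(tt[settle])
          }
        }
        zlow[idx] <- 0
      } else if (e$type == "final_lead") {
        fx[idx] <- e$x
        pitch[idx] <- lin_interp(c(e$t0, e$lr_end, e$t1),
                                 c(PITCH_IC, 0, 0))(tt)
        zlow[idx] <- 0
      }
    }

    fz <- .pivot_z(pitch, zlow)
    quat <- t(vapply(pitch, quat_pitch, numeric(4)))
    R31 <- -sin(pitch); R33 <- cos(pitch)
    ankle_x <- fx + ANKLE_OFFSET[1] * cos(pitch) + ANKLE_OFFSET[3] * sin(pitch)
    ankle_z <- fz + ANKLE_OFFSET[1] * R31 + ANKLE_OFFSET[3] * R33
    knee_x <- ankle_x + shank * sin(phi)
    knee_z <- ankle_z + shank * cos(phi)

    out[[paste0(leg, "_foot_pos_x")]] <- fx
    out[[paste0(leg, "_foot_pos_y")]] <- rep(y, n)
    out[[paste0(leg, "_foot_pos_z")]] <- fz
    out[[paste0(leg, "_foot_quat_w")]] <- quat[, 1]
    out[[paste0(leg, "_foot_quat_x")]] <- quat[, 2]
    out[[paste0(leg, "_foot_quat_y")]] <- quat[, 3]
    out[[paste0(leg, "_foot_quat_z")]] <- quat[, 4]
    out[[paste0(leg, "_ankle_x")]] <- ankle_x
    out[[paste0(leg, "_ankle_y")]] <- rep(y, n)
    out[[paste0(leg, "_ankle_z")]] <- ankle_z
    out[[paste0(leg, "_knee_x")]] <- knee_x
    out[[paste0(leg, "_knee_y")]] <- rep(y, n)
    out[[paste0(leg, "_knee_z")]] <- knee_z
  }
  out
}

# --- force plates -----------------------------------------------------------

# two-peak vertical GRF template on the stance-normalized clock u in [0,1]
#' @keywords internal
#' @noRd
.grf_template <- function() {
  lin_interp(c(0, 0.129, 0.2097, 0.371, 0.50, 0.677, 0.806, 0.903, 1),
             c(0, 1.20, 1.20, 0.80, 0.65, 0.88, 1.10, 0.65, 0))
}

#' @keywords internal
#' @noRd
.heel_share_template <- function() {
  lin_interp(c(0, 0.1613, 0.4839, 1), c(1, 1, 0, 0))
}

#' Synthesize force-plate channels
#'
#' Builds the four plate wrenches (toe and heel plate per foot). The
#' per-foot vertical force follows a two-peak profile rising from zero at
#' initial contact to 120\% body weight at the end of the loading response
#' and decaying to zero at toe-off; the load splits between heel and toe
#' plates so the heel plate leads at initial contact and the toe plate
#' leads after mid-stance. Plate pitch torques are set so that the
#' moment-balance ZMP of the synthesized wrenches reproduces the
#' simulator's commanded ZMP exactly (before noise).
#'
#' @inheritParams synthesize_foot_kinematics
#' @param kinematics The foot-kinematics channels (for the plate poses).
#' @return Data frame of per-sample plate channels.
#' @export
synthesize_force_plates <- function(sim, subject = sim$scenario$subject,
                                    kinematics = NULL) {
  if (is.null(kinematics)) kinematics <- synthesize_foot_kinematics(sim, subject)
  sched <- sim$schedule_internal
  times <- sim$states$time_s
  n <- length(times)
  bw <- subject$mass * 9.81
  grf <- .grf_template(); share <- .heel_share_template()

  fz <- list(); hs <- list()
  for (plan in sim$plans) {
    leg <- plan$leg
    F <- numeric(n); h <- numeric(n)
    for (e in plan$episodes) {
      idx <- which(times >= e$t0 - 1e-9 & times <= e$t1 + 1e-9)
      if (length(idx) == 0L) next
      tt <- times[idx]
      if (e$type == "initial") {
        k1_first <- abs(e$tst_end - e$t1) < 1e-9   # first stepping leg
        if (k1_first) {
          F[idx] <- lin_interp(c(e$t0, e$t1 - 0.2, e$t1), c(0.5, 0.5, 0))(tt)
          h[idx] <- lin_interp(c(e$t0, e$t1 - 0.15, e$t1 - 0.1, e$t1),
                               c(0.5, 0.5, 0, 0))(tt)
        } else {
          to1 <- sched$to[1]
          F[idx] <- lin_interp(
            c(e$t0, to1 - 0.2, to1, e$tst_end, e$t1 - 0.07, e$t1),
            c(0.5, 0.5, 1.0, 1.0, 0.6, 0))(tt)
          h[idx] <- lin_interp(
            c(e$t0, e$mst_end - 0.05, e$mst_end, e$t1),
            c(0.5, 0.5, 0, 0))(tt)
        }
      } else if (e$type == "swing") {
        F[idx] <- 0; h[idx] <- 0
      } else if (e$type == "steady") {
        u <- (tt - e$t0) / e$stance
        F[idx] <- grf(u); h[idx] <- share(u)
      } else if (e$type == "final_trailing") {
        u <- (tt - e$t0) / e$stance
        Fu <- grf(pmin(u, 0.806))
        taper <- lin_interp(c(e$tst_end, e$psw_end), c(1, 0))(tt)
        taper[tt < e$tst_end] <- 1; taper[tt > e$psw_end] <- 0
        F[idx] <- Fu * taper
        h[idx] <- share(u)
      } else if (e$type == "final_lead") {
        st <- plan$stance_dur
        u <- (tt - e$t0) / st
        F[idx] <- lin_interp(c(0, 0.1613, 0.2097, 0.45, 1e3),
                             c(0, 1.20, 1.20, 1.0, 1.0))(u)
        h[idx] <- lin_interp(c(0, 0.1613, 0.45, 1e3),
                             c(1, 1, 0.5, 0.5))(u)
      } else if (e$type == "support_only") {
        F[idx] <- lin_interp(
          c(e$t0, sched$to[1] - 0.2, sched$to[1], sched$hc[1], e$unload, e$t1),
          c(0.5, 0.5, 1.0, 1.0, 0, 0))(tt)
        h[idx] <- 0.5
      }
    }
    fz[[leg]] <- F * bw
    hs[[leg]] <- h
  }

  out <- data.frame(time_s = times)
  plate_xyz <- list()
  for (leg in c("left", "right")) {
    pos <- as.matrix(kinematics[paste0(leg, "_foot_pos_", c("x", "y", "z"))])
    qw <- kinematics[[paste0(leg, "_foot_quat_w")]]
    qy <- kinematics[[paste0(leg, "_foot_quat_y")]]
    pitch <- 2 * atan2(qy, qw)
    cp <- cos(pitch); sp <- sin(pitch)
    for (part in c("toe", "heel")) {
      off <- if (part == "toe") PLATE_TOE else PLATE_HEEL
      px <- pos[, 1] + off[1] * cp + off[3] * sp
      pz <- pos[, 3] - off[1] * sp + off[3] * cp
      w <- if (part == "heel") hs[[leg]] else 1 - hs[[leg]]
      f <- fz[[leg]] * w
      pre <- paste0(leg, "_", part)
      out[[paste0(pre, "_pos_x")]] <- px
      out[[paste0(pre, "_pos_y")]] <- pos[, 2]
      out[[paste0(pre, "_pos_z")]] <- pz
      out[[paste0(pre, "_f_x")]] <- 0
      out[[paste0(pre, "_f_y")]] <- 0
      out[[paste0(pre, "_f_z")]] <- f
      out[[paste0(pre, "_n_x")]] <- 0
      out[[paste0(pre, "_n_y")]] <- 0   # filled below
      out[[paste0(pre, "_n_z")]] <- 0
      plate_xyz[[pre]] <- list(px = px, f = f)
    }
  }

  # pitch torques so the measured ZMP reproduces the commanded ZMP exactly
  fz_tot <- Reduce(`+`, lapply(plate_xyz, function(p) p$f))
  lever <- Reduce(`+`, lapply(plate_xyz, function(p) p$px * p$f))
  deficit <- sim$states$true_zmp_x * fz_tot - lever
  loaded <- fz_tot > 1e-9
  for (pre in names(plate_xyz)) {
    ny <- numeric(n)
    ny[loaded] <- -deficit[loaded] * plate_xyz[[pre]]$f[loaded] / fz_tot[loaded]
    out[[paste0(pre, "_n_y")]] <- ny
  }
  out
}

# --- turning ---------------------------------------------------------------

#' @keywords internal
#' @noRd
.smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

# Map a straight (path-frame) recording into the world frame of a turning
# walk: at each sample a rigid yaw rotation about the waist ground point.
#' @keywords internal
#' @noRd
.apply_turn <- function(df, sc, sched) {
  t <- df$time_s
  t_c <- sched$hc[min(sc$turn_step, sched$n)]
  theta <- (sc$turn_angle * pi / 180) *
    .smoothstep((t - (t_c - 0.6)) / 1.2)
  wx <- df$waist_pos_x; wy <- df$waist_pos_y
  # global waist path: integrate the rotated path velocity
  n <- length(t)
  gx <- numeric(n); gy <- numeric(n)
  gx[1] <- wx[1]; gy[1] <- wy[1]
  for (i in 2:n) {
    th <- (theta[i] + theta[i - 1]) / 2
    dxy <- c(wx[i] - wx[i - 1], wy[i] - wy[i - 1])
    gx[i] <- gx[i - 1] + cos(th) * dxy[1] - sin(th) * dxy[2]
    gy[i] <- gy[i - 1] + sin(th) * dxy[1] + cos(th) * dxy[2]
  }
  ct <- cos(theta); st <- sin(theta)
  rot_point <- function(x, y) {
    rx <- x - wx; ry <- y - wy
    list(x = gx + ct * rx - st * ry, y = gy + st * rx + ct * ry)
  }
  rot_vec <- function(x, y) list(x = ct * x - st * y, y = st * x + ct * y)

  pos_groups <- c("com", "waist_pos",
                  paste0(rep(c("left", "right"), each = 4),
                         rep(c("_foot_pos", "_ankle", "_knee"), 2), ""))
  pos_groups <- c("com", "waist_pos",
                  as.vector(outer(c("left", "right"),
                                  c("_foot_pos", "_ankle", "_knee"),
                                  paste0)),
                  as.vector(outer(c("left", "right"),
                                  c("_toe_pos", "_heel_pos"), paste0)))
  for (gp in pos_groups) {
    cx <- paste0(gp, "_x"); cy <- paste0(gp, "_y")
    if (!all(c(cx, cy) %in% names(df))) next
    p <- rot_point(df[[cx]], df[[cy]])
    df[[cx]] <- p$x; df[[cy]] <- p$y
  }
  vec_groups <- c("dcom", as.vector(outer(c("left", "right"),
                                          c("_toe_f", "_heel_f",
                                            "_toe_n", "_heel_n"), paste0)))
  for (gp in vec_groups) {
    cx <- paste0(gp, "_x"); cy <- paste0(gp, "_y")
    if (!all(c(cx, cy) %in% names(df))) next
    p <- rot_vec(df[[cx]], df[[cy]])
    df[[cx]] <- p$x; df[[cy]] <- p$y
  }
  for (leg in c("left", "right")) {
    qc <- paste0(leg, "_foot_quat_", c("w", "x", "y", "z"))
    q <- as.matrix(df[qc])
    for (i in seq_len(n)) q[i, ] <- quat_multiply(quat_yaw(theta[i]), q[i, ])
    df[qc] <- q
  }
  qc <- paste0("chest_quat_", c("w", "x", "y", "z"))
  df[[qc[1]]] <- cos(theta / 2); df[[qc[2]]] <- 0; df[[qc[3]]] <- 0
  df[[qc[4]]] <- sin(theta / 2)
  df
}

# --- main entry -------------------------------------------------------------

#' Simulate a closed-loop synthetic walk
#'
#' Integrates the COM under the bilateral capture-point MPC law with
#' option-B switching, then synthesizes foot kinematics and force-plate
#' channels consistent with the ground-truth phase timeline. Deterministic
#' given the scenario seed.
#'
#' @param scenario A [walk_scenario()].
#' @return An object of class \code{gait_simulation}: list with
#'   \code{recording} (a \code{gait_recording}), \code{truth} (ground-truth
#'   \code{phase_timelines}), \code{windows} (option-B fit windows),
#'   \code{params} (true \code{pendulum_params}), \code{landings} and the
#'   \code{scenario}.
#' @examples
#' sim <- simulate_walk(walk_scenario(n_steps = 4, noise = NULL))
#' sim$recording
#' @export
simulate_walk <- function(scenario) {
  stopifnot(inherits(scenario, "walk_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  sched <- .walk_schedule(sc)
  states <- .integrate_walk(sc, sched)
  plans <- list(.leg_plan(sc, sched, "left"), .leg_plan(sc, sched, "right"))
  names(plans) <- c("left", "right")
  truth <- .truth_timeline(plans, sched$t_end)

  core <- list(states = states, schedule_internal = sched, plans = plans,
               scenario = sc)

  kin <- synthesize_foot_kinematics(core)
  plates <- synthesize_force_plates(core, kinematics = kin)

  t <- states$time_s
  com_y <- 0.02 * sin(pi * pmax(t - sc$lead_in, 0) / sc$step_duration)
  dcom_y <- 0.02 * pi / sc$step_duration *
    cos(pi * pmax(t - sc$lead_in, 0) / sc$step_duration) * (t > sc$lead_in)
  df <- data.frame(time_s = t,
                   com_x = states$x, com_y = com_y,
                   com_z = sc$params$z_com,
                   dcom_x = states$v, dcom_y = dcom_y, dcom_z = 0,
                   waist_pos_x = states$x, waist_pos_y = com_y,
                   waist_pos_z = 0.6 * sc$subject$height,
                   chest_quat_w = 1, chest_quat_x = 0,
                   chest_quat_y = 0, chest_quat_z = 0)
  df <- cbind(df, kin[-1], plates[-1])
  df$true_zmp_x <- states$true_zmp_x

  if (sc$kind == "turn_walk") df <- .apply_turn(df, sc, sched)

  if (!is.null(sc$noise)) {
    nz <- sc$noise
    add_noise <- function(cols, sd) {
      if (is.null(sd) || sd <= 0) return()
      for (cl in intersect(cols, names(df)))
        df[[cl]] <<- df[[cl]] + stats::rnorm(nrow(df), 0, sd)
    }
    pos_cols <- grep("^(com_|waist_pos_|left_|right_)", names(df), value = TRUE)
    pos_cols <- grep("(pos_|ankle_|knee_|^com_)", pos_cols, value = TRUE)
    add_noise(pos_cols, nz$pos)
    add_noise(paste0("dcom_", c("x", "y", "z")), nz$vel)
    add_noise(grep("_f_[xyz]$", names(df), value = TRUE), nz$force)
    add_noise(grep("_n_[xyz]$", names(df), value = TRUE), nz$torque)
  }

  rec <- gait_recording(df, frame = "global")

  windows <- data.frame(
    window = seq_len(sched$n),
    leg = sched$legs,
    t_start = sched$to,
    t_end = c(sched$to[-1], sched$t_end),
    hc = sched$hc,
    T_next = c(sched$hc[-1], Inf),
    x_sd = sched$land_x,
    x_sd_next = c(sched$land_x[-1], sched$land_x[sched$n]),
    x_p_pre = c(0, sched$land_x[-sched$n]),
    x_p_post = sched$land_x,
    stringsAsFactors = FALSE)

  structure(list(
    recording = rec, truth = truth, windows = windows,
    params = sc$params,
    landings = data.frame(step = seq_len(sched$n), leg = sched$legs,
                          time = sched$hc, x = sched$land_x),
    scenario = sc, states = states,
    schedule_internal = sched, plans = plans
  ), class = "gait_simulation")
}

#' @export
print.gait_simulation <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("synthetic %s: %d step(s) of %.2f m at %.2f s/step, %s\n",
              sc$kind, sc$n_steps, sc$stride, sc$step_duration,
              if (is.null(sc$noise)) "noiseless" else "with sensor noise"))
  cat(sprintf("  controller: zeta1 = %.3g, zeta2 = %.3g 1/s; %d samples at %g Hz\n",
              sc$params$zeta1, sc$params$zeta2, nrow(x$recording),
              sc$sample_rate))
  invisible(x)
}

#' @export
plot.gait_simulation <- function(x, ...) {
  rec <- x$recording
  graphics::plot(rec$time_s, rec$com_x, type = "l", xlab = "time [s]",
                 ylab = "position [m]", main = "COM and model ZMP", ...)
  graphics::lines(rec$time_s, x$states$true_zmp_x, col = "red")
  graphics::legend("topleft", c("COM", "model ZMP"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
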