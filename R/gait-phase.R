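# Rule-based detection of the seven Perry gait phases per leg from
# foot-shape kinematics and plate forces, plus gait-cycle statistics.

PHASE_LEVELS <- c("LoadingResponse", "MidStance", "TerminalStance", "PreSwing",
                  "InitialSwing", "MidSwing", "TerminalSwing")

#' Detector thresholds
#'
#' Tunable thresholds of the gait-phase state machine. Defaults are design
#' choices recorded in the output metadata (the detection rules themselves
#' specify only "a value near 0" for the force criteria).
#'
#' @param floor_contact_dist Foot lowest point height (m) counted as floor
#'   contact; default 10 mm.
#' @param foot_flat_dist Foot highest point height (m) below which the foot
#'   counts as flat; default 25 mm.
#' @param clearance_dist Foot lowest point height (m) above which the foot
#'   counts as clearing the floor in swing; default 20 mm.
#' @param force_on Vertical plate force threshold as a fraction of body
#'   weight; default 0.03 (3\% BW).
#' @param knee_ankle_align_tol Horizontal knee-ankle alignment tolerance
#'   (m); default 20 mm.
#' @param debounce Number of consecutive samples a condition must hold;
#'   default 3.
#' @return A list of class \code{detector_thresholds}.
#' @export
detector_thresholds <- function(floor_contact_dist = 0.010,
                                foot_flat_dist = 0.025,
                                clearance_dist = 0.020,
                                force_on = 0.03,
                                knee_ankle_align_tol = 0.020,
                                debounce = 3L) {
  vals <- c(floor_contact_dist, foot_flat_dist, clearance_dist, force_on,
            knee_ankle_align_tol, debounce)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all detector thresholds must be positive")
  structure(list(floor_contact_dist = floor_contact_dist,
                 foot_flat_dist = foot_flat_dist,
                 clearance_dist = clearance_dist,
                 force_on = force_on,
                 knee_ankle_align_tol = knee_ankle_align_tol,
                 debounce = as.integer(debounce)),
            class = "detector_thresholds")
}

# Per-leg signal table used by the state machine.
#' @keywords internal
#' @noRd
.phase_signals <- function(recording, leg, outline) {
  opp <- if (leg == "left") "right" else "left"
  n <- nrow(recording)
  t <- recording$time_s
  col <- function(nm) if (nm %in% names(recording)) recording[[nm]] else NULL

  foot_lowhigh <- function(side) {
    pos_cols <- paste0(side, "_foot_pos_", c("x", "y", "z"))
    quat_cols <- paste0(side, "_foot_quat_", c("w", "x", "y", "z"))
    if (!all(c(pos_cols, quat_cols) %in% names(recording)))
      return(NULL)
    pos <- as.matrix(recording[pos_cols])
    quat <- as.matrix(recording[quat_cols])
    lo <- numeric(n); hi <- numeric(n)
    pts <- cbind(outline, 0)
    for (i in seq_len(n)) {
      R <- quat_to_matrix(quat_normalize(quat[i, ], warn = FALSE))
      z <- pts %*% R[3, ] + pos[i, 3]
      lo[i] <- min(z); hi[i] <- max(z)
    }
    list(low = lo, high = hi)
  }

  # travel direction: unit horizontal COM velocity, smoothed over about a
  # gait cycle so lateral sway does not tilt the axis, forward-filled
  vx <- recording$dcom_x; vy <- recording$dcom_y
  k <- min(61L, n - (1 - n %% 2))  # odd window <= n
  if (k >= 3) {
    sm <- function(v) {
      f <- stats::filter(v, rep(1 / k, k), sides = 2)
      f[is.na(f)] <- v[is.na(f)]
      as.numeric(f)
    }
    vx <- sm(vx); vy <- sm(vy)
  }
  spd <- sqrt(vx^2 + vy^2)
  dirx <- rep(1, n); diry <- rep(0, n)
  ok <- spd > 0.05
  dirx[ok] <- vx[ok] / spd[ok]; diry[ok] <- vy[ok] / spd[ok]
  if (any(ok)) {  # carry last valid heading through slow samples
    idx <- cumsum(ok); idx[idx == 0] <- NA
    src <- which(ok)
    fill <- !ok & !is.na(idx)
    dirx[fill] <- dirx[src[idx[fill]]]; diry[fill] <- diry[src[idx[fill]]]
  }

  proj <- function(px, py) px * dirx + py * diry

  own_lh <- foot_lowhigh(leg)
  opp_lh <- foot_lowhigh(opp)

  heel_fz <- col(paste0(leg, "_heel_f_z"))
  toe_fz <- col(paste0(leg, "_toe_f_z"))
  opp_heel_fz <- col(paste0(opp, "_heel_f_z"))

  ankle <- cbind(col(paste0(leg, "_ankle_x")), col(paste0(leg, "_ankle_y")))
  opp_ankle <- cbind(col(paste0(opp, "_ankle_x")), col(paste0(opp, "_ankle_y")))
  knee <- cbind(col(paste0(leg, "_knee_x")), col(paste0(leg, "_knee_y")))
  if (is.null(ankle) || is.null(opp_ankle) || ncol(ankle) < 2)
    stop("recording lacks ankle channels for both legs (needed by the swing rules)")
  if (is.null(knee) || ncol(knee) < 2)
    stop("recording lacks knee channels for leg ", leg)

  list(
    t = t, n = n,
    heel_fz = heel_fz, toe_fz = toe_fz, opp_heel_fz = opp_heel_fz,
    low = own_lh$low, high = own_lh$high, opp_low = opp_lh$low,
    ankle_p = proj(ankle[, 1], ankle[, 2]),
    opp_ankle_p = proj(opp_ankle[, 1], opp_ankle[, 2]),
    knee_align = abs(proj(knee[, 1], knee[, 2]) - proj(ankle[, 1], ankle[, 2])),
    force_mode = !is.null(heel_fz) && !is.null(toe_fz) && !is.null(opp_heel_fz)
  )
}

# condition held for `d` consecutive samples starting at k (clipped at end)
#' @keywords internal
#' @noRd
.held <- function(cond, k, d) {
  idx <- k:min(k + d - 1L, length(cond))
  all(cond[idx])
}

#' Detect the seven Perry gait phases
#'
#' Runs a rule-based state machine per leg over a recording. Force criteria
#' (plate vertical forces crossing \code{force_on} x body weight) are
#' primary when the plate channels are present; the foot-shape kinematic
#' criteria are the fallback and a cross-check (disagreements beyond 5
#' samples are collected in the \code{diagnostics} attribute). Transitions:
#' initial contact at a heel-force rise (or the foot lowest point reaching
#' the floor); loading response ends at the toe-force rise (foot flat);
#' mid-stance ends at the heel-force fall (heel rise); terminal stance ends
#' at the opposite foot's initial contact; pre-swing ends at the toe-force
#' fall (toe-off, foot clearing the floor); initial swing ends when the
#' swinging ankle passes the opposite ankle along the travel direction;
#' mid-swing ends when knee and ankle align horizontally. Several
#' transitions may fire on one sample, emitting zero-duration phases (as at
#' the start of a stepping motion, where terminal stance runs directly into
#' toe-off and initial and mid-swing activate together).
#'
#' @param recording A \code{gait_recording} with foot pose, ankle/knee and
#'   (optionally) plate force channels for both feet.
#' @param model A \code{subject_model} (for body weight); if \code{NULL}
#'   body weight is estimated as the median loaded total vertical force.
#' @param thresholds A [detector_thresholds()].
#' @param outline Insole outline used for the foot lowest/highest points.
#' @return An object of class \code{phase_timelines}: list with per-leg
#'   \code{data.frame(leg, phase, t_start, t_end)}, an \code{events} data
#'   frame, the thresholds used, and diagnostics.
#' @export
detect_phases <- function(recording, model = NULL,
                          thresholds = detector_thresholds(),
                          outline = default_insole_outline()) {
  stopifnot(inherits(recording, "gait_recording"))
  g <- 9.81
  bw <- if (!is.null(model)) model$mass * g else {
    fz_cols <- grep("_f_z$", names(recording), value = TRUE)
    if (length(fz_cols) == 0L) stop("no subject model and no plate channels: cannot scale force threshold")
    tot <- rowSums(as.matrix(recording[fz_cols]))
    stats::median(tot[tot > 50])
  }
  f_on <- thresholds$force_on * bw

  run_leg <- function(leg) {
    sig <- .phase_signals(recording, leg, outline)
    d <- thresholds$debounce
    n <- sig$n; t <- sig$t
    fm <- sig$force_mode

    # each criterion is a fire vector (instant condition) plus a hold
    # vector (the level that must persist for `debounce` samples); for
    # edge criteria the edge fires and the level must then hold
    level <- function(x) list(fire = x, hold = x)
    edge_up <- function(x, thr) {
      lv <- x >= thr
      list(fire = c(FALSE, lv[-1] & !lv[-length(x)]), hold = lv)
    }
    edge_down <- function(x, thr) {
      lv <- x < thr
      list(fire = c(FALSE, lv[-1] & !lv[-length(x)]), hold = lv)
    }

    crit <- list()
    if (fm) {
      crit$ic <- edge_up(sig$heel_fz, f_on)
      crit$lr_end <- level(sig$toe_fz >= f_on)
      crit$mst_end <- level(sig$heel_fz < f_on)
      crit$tst_end <- edge_up(sig$opp_heel_fz, f_on)
      crit$psw_end <- level(sig$toe_fz < f_on)
    } else {
      crit$ic <- edge_down(sig$low, thresholds$floor_contact_dist)
      crit$lr_end <- level(sig$high < thresholds$foot_flat_dist)
      crit$mst_end <- level(sig$high >= thresholds$foot_flat_dist)
      crit$tst_end <- edge_down(sig$opp_low, thresholds$floor_contact_dist)
      crit$psw_end <- level(sig$low >= thresholds$clearance_dist)
    }
    crit$isw_end <- level(sig$ankle_p >= sig$opp_ankle_p - 1e-9)
    crit$msw_end <- level(sig$knee_align <= thresholds$knee_ankle_align_tol)
    crit$tsw_end <- crit$ic

    # kinematic shadow criteria for the cross-check (force mode only)
    shadow <- if (fm && !is.null(sig$low)) list(
      ic = c(FALSE, sig$low[-1] < thresholds$floor_contact_dist &
                      sig$low[-n] >= thresholds$floor_contact_dist),
      lr_end = sig$high < thresholds$foot_flat_dist,
      mst_end = sig$high >= thresholds$foot_flat_dist
    ) else NULL

    exit_of <- c(LoadingResponse = "lr_end", MidStance = "mst_end",
                 TerminalStance = "tst_end", PreSwing = "psw_end",
                 InitialSwing = "isw_end", MidSwing = "msw_end",
                 TerminalSwing = "tsw_end")
    next_of <- c(LoadingResponse = "MidStance", MidStance = "TerminalStance",
                 TerminalStance = "PreSwing", PreSwing = "InitialSwing",
                 InitialSwing = "MidSwing", MidSwing = "TerminalSwing",
                 TerminalSwing = "LoadingResponse")

    on_ground <- if (fm) (sig$heel_fz[1] >= f_on || sig$toe_fz[1] >= f_on)
                 else sig$low[1] < thresholds$floor_contact_dist
    state <- if (on_ground) "MidStance" else "MidSwing"

    phases <- list()
    events <- list()
    diagnostics <- list()
    t_enter <- t[1]

    emit <- function(phase, from, to) {
      phases[[length(phases) + 1L]] <<- data.frame(
        leg = leg, phase = phase, t_start = from, t_end = to,
        stringsAsFactors = FALSE)
    }
    note_event <- function(name, time) {
      events[[length(events) + 1L]] <<- data.frame(
        leg = leg, event = name, time = time, stringsAsFactors = FALSE)
    }
    cross_check <- function(name, k) {
      if (is.null(shadow) || is.null(shadow[[name]])) return()
      win <- max(1L, k - 10L):min(n, k + 10L)
      hit <- win[shadow[[name]][win]]
      gap <- if (length(hit) == 0L) Inf else min(abs(hit - k))
      if (gap > 5)
        diagnostics[[length(diagnostics) + 1L]] <<- data.frame(
          leg = leg, criterion = name, sample = k, kinematic_gap = gap,
          stringsAsFactors = FALSE)
    }

    for (k in seq_len(n)) {
      for (hop in 1:7) {  # allow chained (zero-duration) transitions
        cond <- crit[[exit_of[[state]]]]
        fired <- cond$fire[k] && .held(cond$hold, k, d)
        skipped <- FALSE
        if (!fired && state == "TerminalStance") {
          # stepping start: toe-off arrives with no opposite initial contact;
          # pre-swing collapses to zero duration
          pcond <- crit$psw_end
          if (pcond$fire[k] && .held(pcond$hold, k, d) &&
              (if (fm) sig$toe_fz[max(k - 1, 1)] >= f_on else TRUE)) {
            fired <- TRUE; skipped <- TRUE
          }
        }
        if (!fired) break
        ev_name <- exit_of[[state]]
        if (state == "TerminalSwing") {
          note_event("IC", t[k]); cross_check("ic", k)
        } else {
          note_event(ev_name, t[k])
          cross_check(ev_name, k)
        }
        emit(state, t_enter, t[k])
        if (skipped) {
          emit("PreSwing", t[k], t[k])
          note_event("psw_end", t[k])
          state <- "InitialSwing"
        } else {
          state <- next_of[[state]]
        }
        t_enter <- t[k]
        if (state == "LoadingResponse" && hop > 1) break
      }
    }
    emit(state, t_enter, t[n])

    list(timeline = do.call(rbind, phases),
         events = if (length(events)) do.call(rbind, events) else
           data.frame(leg = character(), event = character(), time = numeric()),
         diagnostics = if (length(diagnostics)) do.call(rbind, diagnostics) else NULL)
  }

  left <- run_leg("left"); right <- run_leg("right")
  structure(list(
    left = structure(left$timeline, class = c("phase_timeline", "data.frame")),
    right = structure(right$timeline, class = c("phase_timeline", "data.frame")),
    events = rbind(left$events, right$events),
    thresholds = thresholds,
    body_weight_n = bw,
    diagnostics = rbind(left$diagnostics, right$diagnostics)
  ), class = "phase_timelines")
}

#' @export
print.phase_timelines <- function(x, ...) {
  for (leg in c("left", "right")) {
    tl <- x[[leg]]
    ics <- x$events$time[x$events$leg == leg & x$events$event == "IC"]
    cat(sprintf("%s leg: %d phase intervals, %d initial contacts\n",
                leg, nrow(tl), length(ics)))
  }
  invisible(x)
}

# initial-contact times for one leg
#' @keywords internal
#' @noRd
.ic_times <- function(timelines, leg) {
  ev <- timelines$events
  sort(ev$time[ev$leg == leg & ev$event == "IC"])
}

#' Gait-cycle statistics
#'
#' Per-cycle phase durations normalized to 100\% of the gait cycle (initial
#' contact to next ipsilateral initial contact), and the stance/swing split
#' (stance = loading response + mid-stance + terminal stance + pre-swing).
#' By default only steady-state cycles are used: cycles overlapping the
#' first or last heel contact of the bout (walk start and braking
#' transients) are excluded.
#'
#' @param timelines A \code{phase_timelines} from [detect_phases()] (or a
#'   single-leg \code{phase_timeline} data frame).
#' @param steady_only Exclude transient cycles (default \code{TRUE}).
#' @return A list of class \code{cycle_statistics} with \code{per_cycle}
#'   (one row per cycle and phase, percentage of cycle), \code{summary}
#'   (mean percentage per leg and phase), and \code{stance_swing} (mean
#'   stance and swing percentage per leg plus pooled).
#' @export
cycle_statistics <- function(timelines, steady_only = TRUE) {
  if (inherits(timelines, "phase_timeline") || is.data.frame(timelines)) {
    tl <- timelines
    leg <- tl$leg[1]
    ics <- sort(tl$t_start[tl$phase == "LoadingResponse"])
    fake <- list(events = data.frame(
      leg = rep(leg, length(ics)), event = rep("IC", length(ics)),
      time = ics))
    fake[[leg]] <- tl
    timelines <- structure(fake, class = "phase_timelines")
    legs <- leg
  } else legs <- intersect(c("left", "right"), names(timelines))

  all_ics <- sort(unlist(lapply(legs, function(l) .ic_times(timelines, l))))
  rows <- list()
  for (leg in legs) {
    tl <- timelines[[leg]]
    ics <- .ic_times(timelines, leg)
    if (length(ics) < 2L) next
    for (ci in seq_len(length(ics) - 1L)) {
      a <- ics[ci]; b <- ics[ci + 1L]
      transient <- length(all_ics) >= 2L &&
        (a < all_ics[2] - 1e-9 || b > all_ics[length(all_ics) - 1L] + 1e-9)
      if (steady_only && transient) next
      seg <- tl[tl$t_start >= a - 1e-9 & tl$t_end <= b + 1e-9, , drop = FALSE]
      dur <- vapply(PHASE_LEVELS, function(p)
        sum(seg$t_end[seg$phase == p] - seg$t_start[seg$phase == p]), 0)
      pct <- 100 * dur / (b - a)
      rows[[length(rows) + 1L]] <- data.frame(
        leg = leg, cycle = ci, phase = PHASE_LEVELS, percent = pct,
        t_start = a, t_end = b, transient = transient,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(rows) == 0L)
    stop("no complete ", if (steady_only) "steady " else "",
         "gait cycle in the timeline")
  per_cycle <- do.call(rbind, rows)

  summ <- stats::aggregate(percent ~ leg + phase, data = per_cycle, FUN = mean)
  stance_phases <- c("LoadingResponse", "MidStance", "TerminalStance", "PreSwing")
  ss <- lapply(split(per_cycle, interaction(per_cycle$leg, per_cycle$cycle, drop = TRUE)),
               function(d) data.frame(
                 leg = d$leg[1],
                 stance = sum(d$percent[d$phase %in% stance_phases]),
                 swing = sum(d$percent[!(d$phase %in% stance_phases)])))
  ss <- do.call(rbind, ss)
  stance_swing <- stats::aggregate(cbind(stance, swing) ~ leg, data = ss, FUN = mean)
  structure(list(per_cycle = per_cycle, summary = summ,
                 stance_swing = stance_swing,
                 stance_mean = mean(ss$stance), swing_mean = mean(ss$swing)),
            class = "cycle_statistics")
}

#' @export
print.cycle_statistics <- function(x, ...) {
  cat(sprintf("gait-cycle statistics over %d cycle(s)\n",
              nrow(unique(x$per_cycle[c("leg", "cycle")]))))
  cat(sprintf("  stance %.1f%% / swing %.1f%% (pooled)\n",
              x$stance_mean, x$swing_mean))
  for (i in seq_len(nrow(x$stance_swing)))
    cat(sprintf("  %s: stance %.1f%% / swing %.1f%%\n",
                x$stance_swing$leg[i], x$stance_swing$stance[i],
                x$stance_swing$swing[i]))
  invisible(x)
}

#' Export a phase timeline as a per-sample label column
#'
#' @param timelines A \code{phase_timelines}.
#' @param recording The recording the timeline was detected on.
#' @return The recording with added \code{left_phase} and
#'   \code{right_phase} character columns.
#' @export
label_recording <- function(timelines, recording) {
  for (leg in c("left", "right")) {
    tl <- timelines[[leg]]
    lab <- rep(NA_character_, nrow(recording))
    for (i in seq_len(nrow(tl))) {
      sel <- recording$time_s >= tl$t_start[i] & recording$time_s < tl$t_end[i]
      lab[sel] <- tl$phase[i]
    }
    lab[is.na(lab)] <- tl$phase[nrow(tl)]
    recording[[paste0(leg, "_phase")]] <- lab
  }
  recording
}
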