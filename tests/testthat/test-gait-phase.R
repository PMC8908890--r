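test_that("detector recovers ground-truth events within one sample on clean data", {
  sim <- sim_walk_clean()
  det <- detect_phases(sim$recording, model = sim$scenario$subject)
  tru <- sim$truth$events
  # steady portion: between the second and second-to-last heel contact
  ics <- sort(tru$time[tru$event == "IC"])
  lo <- ics[2]; hi <- ics[length(ics) - 1]
  steady <- tru[tru$time >= lo & tru$time <= hi, ]
  errs <- vapply(seq_len(nrow(steady)), function(i) {
    d <- match_event(det$events, steady$leg[i], steady$event[i], steady$time[i])
    abs(d - steady$time[i])
  }, 0)
  expect_true(all(is.finite(errs)))
  expect_lte(max(errs), 1 / 60 + 1e-9)
})

test_that("detector stays within three samples at the default noise level", {
  sim <- sim_walk_noisy()
  det <- detect_phases(sim$recording, model = sim$scenario$subject)
  tru <- sim$truth$events
  ics <- sort(tru$time[tru$event == "IC"])
  steady <- tru[tru$time >= ics[2] & tru$time <= ics[length(ics) - 1], ]
  errs <- vapply(seq_len(nrow(steady)), function(i) {
    d <- match_event(det$events, steady$leg[i], steady$event[i], steady$time[i])
    abs(d - steady$time[i])
  }, 0)
  expect_lte(max(errs), 3 / 60 + 1e-9)
})

test_that("stepping motion collapses pre-swing and initial swing to zero duration", {
  sim <- sim_stepping_clean()
  det <- detect_phases(sim$recording, model = sim$scenario$subject)
  leg <- sim$scenario$first_leg
  tl <- det[[leg]]
  psw <- tl[tl$phase == "PreSwing", ][1, ]
  isw <- tl[tl$phase == "InitialSwing", ][1, ]
  expect_equal(psw$t_end - psw$t_start, 0)
  expect_equal(isw$t_end - isw$t_start, 0)
  # terminal stance runs straight into toe-off
  tst <- tl[tl$phase == "TerminalStance", ][1, ]
  expect_equal(tst$t_end, psw$t_start)
})

test_that("standing records emit no swing phases", {
  sim <- sim_walk_clean()
  rec <- sim$recording
  standing <- gait_recording(as.data.frame(rec)[rec$time_s <= 0.45, ],
                             frame = "global")
  det <- detect_phases(standing, model = sim$scenario$subject)
  swing <- c("InitialSwing", "MidSwing", "TerminalSwing")
  expect_false(any(det$left$phase %in% swing))
  expect_false(any(det$right$phase %in% swing))
})

test_that("detection is deterministic and labels never regress in cycle order", {
  sim <- sim_walk_noisy()
  d1 <- detect_phases(sim$recording, model = sim$scenario$subject)
  d2 <- detect_phases(sim$recording, model = sim$scenario$subject)
  expect_identical(d1$left, d2$left)
  expect_identical(d1$right, d2$right)

  order_of <- function(p) match(p, gaitbalance:::PHASE_LEVELS)
  for (leg in c("left", "right")) {
    tl <- d1[[leg]]
    steps <- diff(order_of(tl$phase))
    # successor is either the next phase or the wrap back to loading response
    expect_true(all(steps == 1 | steps == -6))
  }
})

test_that("raising the force threshold never makes initial contact earlier", {
  sim <- sim_walk_clean()
  ic_times <- function(frac) {
    det <- detect_phases(sim$recording, model = sim$scenario$subject,
                         thresholds = detector_thresholds(force_on = frac))
    sort(det$events$time[det$events$event == "IC"])
  }
  lo <- ic_times(0.02); hi <- ic_times(0.10)
  n <- min(length(lo), length(hi))
  expect_true(all(hi[seq_len(n)] >= lo[seq_len(n)] - 1e-9))
})

test_that("cycle statistics report the normal stance/swing split", {
  sim <- sim_walk_clean()
  det <- detect_phases(sim$recording, model = sim$scenario$subject)
  st <- cycle_statistics(det)
  expect_lt(abs(st$stance_mean - 62), 2)
  expect_lt(abs(st$swing_mean - 38), 2)
  # percentages tile the cycle
  per <- st$per_cycle
  for (key in unique(paste(per$leg, per$cycle))) {
    d <- per[paste(per$leg, per$cycle) == key, ]
    expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  }
})

test_that("hand-built equal-duration timeline gives 100/7 percent per phase", {
  phases <- gaitbalance:::PHASE_LEVELS
  tl <- data.frame(leg = "left",
                   phase = rep(c(phases, phases), 1),
                   t_start = seq(0, by = 1, length.out = 14),
                   t_end = seq(1, by = 1, length.out = 14))
  # append the closing loading response so two initial contacts exist
  tl <- rbind(tl, data.frame(leg = "left", phase = "LoadingResponse",
                             t_start = 14, t_end = 15))
  st <- cycle_statistics(structure(tl, class = c("phase_timeline", "data.frame")),
                         steady_only = FALSE)
  expect_equal(unique(round(st$per_cycle$percent, 9)), round(100 / 7, 9))
})

test_that("asymmetric swing fractions produce differing per-side splits", {
  sim <- fixture("asym_walk", function()
    simulate_walk(walk_scenario(n_steps = 6, noise = NULL,
                                swing_frac = c(left = 0.42, right = 0.35))))
  det <- detect_phases(sim$recording, model = sim$scenario$subject)
  st <- cycle_statistics(det)
  sw <- st$stance_swing
  left <- sw$stance[sw$leg == "left"]; right <- sw$stance[sw$leg == "right"]
  expect_gt(abs(left - right), 3)
  expect_lt(left, right)  # longer swing -> shorter stance on the left
})

test_that("cycle statistics refuse a timeline without a complete cycle", {
  tl <- data.frame(leg = "left", phase = "MidStance", t_start = 0, t_end = 1)
  expect_error(cycle_statistics(
    structure(tl, class = c("phase_timeline", "data.frame"))), "cycle")
})
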