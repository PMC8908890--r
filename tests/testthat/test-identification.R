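test_that("segmentation yields option-B windows split at heel contact", {
  sim <- sim_walk_clean()
  segs <- segment_trials(sim$truth,
                         t_end = sim$recording$time_s[nrow(sim$recording)])
  expect_equal(nrow(segs), 6)                      # six windows
  expect_true(all(segs$t_start < segs$hc & segs$hc < segs$t_end))
  expect_equal(segs$leg, sim$landings$leg)         # one window per step
  # legs alternate between consecutive windows
  expect_true(all(segs$leg[-1] != segs$leg[-6]))

  stepping <- sim_stepping_clean()
  segs1 <- segment_trials(stepping$truth,
                          t_end = stepping$recording$time_s[nrow(stepping$recording)])
  expect_equal(nrow(segs1), 1)

  # a standing bout has no toe-offs and therefore no windows
  standing <- structure(list(
    left = stepping$truth$left[1, , drop = FALSE],
    right = stepping$truth$right[1, , drop = FALSE],
    events = data.frame(leg = character(), event = character(),
                        time = numeric())), class = "phase_timelines")
  expect_equal(nrow(segment_trials(standing, t_end = 2)), 0)
})

test_that("segmentation rejects inconsistent event ordering", {
  bad <- structure(list(events = data.frame(
    leg = c("right", "right", "right"),
    event = c("psw_end", "psw_end", "IC"),
    time = c(0.5, 1.0, 1.6)),
    left = data.frame(t_end = 2), right = data.frame(t_end = 2)),
    class = "phase_timelines")
  expect_error(segment_trials(bad, t_end = 2), "inconsistent event ordering")
})

test_that("noiseless recovery of the generating controller is exact", {
  sim <- sim_stepping_clean()
  truth <- sim$params
  fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
                                constraint_product = truth$zeta1 * truth$zeta2,
                                seed = 0, lowpass_hz = NULL)
  expect_lt(abs(fit$zeta1 - truth$zeta1) / truth$zeta1, 0.02)
  expect_lt(abs(fit$zeta2 - truth$zeta2) / truth$zeta2, 0.02)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$zeta1 * fit$zeta2, truth$zeta1 * truth$zeta2,
               tolerance = 1e-9)                   # constraint is exact

  walk <- sim_walk_clean()
  fit2 <- fit_balance_controller(walk$recording, timelines = walk$truth,
                                 lowpass_hz = NULL)
  expect_lt(abs(fit2$zeta1 - 4) / 4, 0.02)
  expect_lt(abs(fit2$zeta2 - 2.16) / 2.16, 0.02)
  # support anchors recover the landing positions
  anchors <- fit2$segments
  pre <- anchors[anchors$half == "pre", ]
  expect_equal(pre$x_p, c(0, walk$landings$x[1:5]), tolerance = 5e-3)
})

test_that("a symmetric controller is recovered as symmetric", {
  sim <- fixture("sym_walk", function()
    simulate_walk(walk_scenario(n_steps = 6, zeta1 = 3, zeta2 = 3,
                                noise = NULL)))
  fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
                                lowpass_hz = NULL)
  expect_lt(abs(fit$zeta1 - fit$zeta2) / fit$zeta1, 0.05)
})

test_that("median parameter recovery under default noise is within 5 percent", {
  z1 <- numeric(10); z2 <- numeric(10); xp_err <- numeric(10)
  xp_true <- c(0, 0.3, 0.3, 0.6, 0.6, 0.9, 0.9, 1.2, 1.2, 1.5, 1.5, 1.8)
  for (s in 1:10) {
    sim <- simulate_walk(walk_scenario(n_steps = 6, seed = 100 + s))
    fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
                                  seed = s)
    z1[s] <- fit$zeta1; z2[s] <- fit$zeta2
    xp_err[s] <- stats::median(abs(fit$x_p - xp_true))
  }
  expect_lt(abs(stats::median(z1) - 4) / 4, 0.05)
  expect_lt(abs(stats::median(z2) - 2.16) / 2.16, 0.05)
  expect_lt(stats::median(xp_err), 0.075)  # 5% of the 1.5 m anchor span
})

test_that("model ZMP trace is consistent with the reported fit error", {
  sim <- sim_walk_clean()
  fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
                                lowpass_hz = NULL)
  tr <- model_zmp_trace(fit)
  expect_equal(attr(tr, "rmse"), fit$rmse, tolerance = 1e-9)
  expect_lt(attr(tr, "rmse"), 1e-6)        # exact model class, no noise
  expect_equal(length(fitted(fit)), fit$n_obs)
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$rmse, tolerance = 1e-6)

  # at the default noise level the residual stays near the sensor noise floor
  noisy <- sim_walk_noisy()
  fitn <- fit_balance_controller(noisy$recording, timelines = noisy$truth)
  zn <- recording_zmp(noisy$recording)
  noise_floor <- sqrt(mean((zn$zmp_x - noisy$recording$true_zmp_x)^2,
                           na.rm = TRUE))
  expect_lt(fitn$rmse, 2 * noise_floor + 0.01)
})

test_that("local-frame fit of a straight walk equals the global fit", {
  sim <- sim_walk_clean()
  fg <- fit_balance_controller(sim$recording, timelines = sim$truth)
  loc <- to_local_frame(sim$recording)
  fl <- fit_balance_controller(loc, timelines = sim$truth)
  expect_equal(coef(fl), coef(fg), tolerance = 1e-3)
  expect_equal(fl$rmse, fg$rmse, tolerance = 1e-6)
})

test_that("local-frame round trip restores the global recording", {
  sim <- sim_turn_clean()
  loc <- to_local_frame(sim$recording)
  back <- from_local_frame(loc)
  num <- vapply(sim$recording, is.numeric, TRUE)
  expect_lt(max(abs(as.matrix(back[num]) - as.matrix(sim$recording[num]))),
            1e-9)
  expect_error(to_local_frame(loc), "already")
})

test_that("the local frame straightens a turning walk", {
  sim <- sim_turn_clean()
  rec <- sim$recording
  loc <- to_local_frame(rec)
  # global forward velocity rotates away; local forward velocity stays positive
  t <- rec$time_s
  steady <- t > 1.5 & t < max(sim$landings$time) - 0.2
  expect_lt(min(rec$dcom_x[steady]), 0.2)       # heading has rotated
  expect_gt(min(loc$dcom_x[steady]), 0.2)       # forward speed preserved

  fit_turn <- fit_balance_controller(loc, timelines = sim$truth)
  straight <- sim_walk_clean()
  fit_straight <- fit_balance_controller(straight$recording,
                                         timelines = straight$truth)
  expect_lt(fit_turn$rmse, 2 * fit_straight$rmse)
  expect_lt(abs(fit_turn$zeta1 - 4) / 4, 0.05)
})

test_that("a non-converged style failure is flagged rather than fatal", {
  sim <- sim_stepping_clean()
  fit <- fit_balance_controller(sim$recording, timelines = sim$truth,
                                n_starts = 1L, seed = 2)
  expect_true(is.logical(fit$converged))
  expect_s3_class(fit, "balance_fit")
})
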