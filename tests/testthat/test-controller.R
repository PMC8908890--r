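test_that("MPC ZMP law limits and anchor behaviour", {
  p <- pendulum_params(4, 2.16)
  # state already on the discounted capture manifold -> no corrective offset
  Tt <- 0.6; t <- 0.2; E <- exp(-4 * (Tt - t))
  x_p <- 0.05; x_sd <- 0.35
  xdot <- 0.3
  x <- x_p + E * (x_sd - x_p) - xdot / 2.16
  expect_equal(mpc_zmp(list(x = x, xdot = xdot),
                       list(x_p = x_p, x_sd = x_sd, T = Tt), t, p),
               x_p, tolerance = 1e-12)
  # infinite-horizon limit: pure braking law x_p + 2 * x_cp
  st <- list(x = 0.05, xdot = 0)
  expect_equal(mpc_zmp(st, list(x_p = 0, x_sd = 1, T = Inf), 0, p), 0.1)
  expect_equal(mpc_zmp(st, list(x_p = 0, x_sd = 1, T = 1e4), 0, p), 0.1,
               tolerance = 1e-9)
  # horizon floor keeps the command finite through t = T
  expect_true(is.finite(mpc_zmp(st, list(x_p = 0, x_sd = 0.3, T = 0.5),
                                0.5, p)))
})

test_that("closed loop under the MPC law meets the terminal capture condition", {
  skip_if_not_installed("deSolve")
  p <- pendulum_params(4, 2.16)
  # the documented stepping case
  task <- list(x_p = 0, x_sd = 0.3, T = 0.6)
  zf <- function(t, y) mpc_zmp(list(x = y[1], xdot = y[2]), task, t, p)
  end <- integrate_pendulum(list(x = 0, xdot = 0), zf, p, 0.6, dt = 2.5e-4)
  expect_lt(abs(capture_point(list(x = end$x, xdot = end$xdot), p$zeta2) - 0.3),
            1e-3)

  # random physiologic tasks
  set.seed(5)
  for (i in 1:8) {
    pp <- pendulum_params(runif(1, 2.5, 5.5), runif(1, 1.5, 3.5))
    tk <- list(x_p = runif(1, -0.1, 0.1), x_sd = runif(1, 0.15, 0.5),
               T = runif(1, 0.4, 0.9))
    s0 <- list(x = runif(1, -0.05, 0.05), xdot = runif(1, -0.1, 0.3))
    zf <- function(t, y) mpc_zmp(list(x = y[1], xdot = y[2]), tk, t, pp)
    end <- integrate_pendulum(s0, zf, pp, tk$T, dt = 2.5e-4)
    cp <- capture_point(list(x = end$x, xdot = end$xdot), pp$zeta2)
    expect_lt(abs(cp - tk$x_sd), 1e-3)
  }
})

test_that("MPC command is continuous in time up to the horizon floor", {
  p <- pendulum_params(4, 2.16)
  task <- list(x_p = 0, x_sd = 0.3, T = 0.6)
  st <- list(x = 0.05, xdot = 0.2)
  tt <- seq(0, 0.5, by = 1e-3)
  cmd <- vapply(tt, function(t) mpc_zmp(st, task, t, p), 0)
  expect_true(all(abs(diff(cmd)) < 0.01))
})

test_that("the law minimizes the squared ZMP offset among terminal-feasible policies", {
  # foot-relative capture coordinate obeys du/dt = zeta1 (u - v);
  # compare the closed-loop optimal trace against random alternatives
  # that reach the same terminal capture point
  z1 <- 4; z2 <- 2.16
  p <- pendulum_params(z1, z2)
  Tt <- 0.6; dt <- 1 / 600
  tt <- seq(0, Tt, by = dt)
  u0 <- 0.05; uT <- 0.3

  # optimal command from the feedback law along its own closed loop
  u <- numeric(length(tt)); v <- numeric(length(tt))
  u[1] <- u0
  for (i in seq_along(tt)) {
    E <- exp(-z1 * max(Tt - tt[i], 1e-3))
    v[i] <- 2 * (u[i] - E * uT) / (1 - E^2)
    if (i < length(tt)) {
      f <- function(ui, vi) z1 * (ui - vi)
      k1 <- f(u[i], v[i]); k2 <- f(u[i] + dt / 2 * k1, v[i])
      k3 <- f(u[i] + dt / 2 * k2, v[i]); k4 <- f(u[i] + dt * k3, v[i])
      u[i + 1] <- u[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  expect_equal(u[length(u)], uT, tolerance = 2e-3)
  j_opt <- zmp_objective(v, 0, dt)

  # terminal constraint as a weighted integral: u(T) depends on v only
  # through I = integral e^{zeta1 (T - s)} v(s) ds
  w <- exp(z1 * (Tt - tt))
  I_opt <- sum(w * v) * dt
  set.seed(9)
  for (k in 1:50) {
    delta <- 0.05 * sin(2 * pi * runif(1, 0.5, 3) * tt + runif(1, 0, 2 * pi)) +
      0.03 * runif(1, -1, 1)
    c0 <- (I_opt - sum(w * (v + delta)) * dt) / (sum(w) * dt)
    v_alt <- v + delta + c0
    expect_equal(sum(w * v_alt) * dt, I_opt, tolerance = 1e-9)
    expect_gte(zmp_objective(v_alt, 0, dt), j_opt - 1e-12)
  }
})

test_that("ZMP objective closed forms", {
  dt <- 0.01
  expect_equal(zmp_objective(rep(0.2, 101), 0.2, dt), 0)
  expect_equal(zmp_objective(rep(0.25, 101), 0.2, dt), 0.05^2 * 1.0,
               tolerance = 1e-12)
  expect_error(zmp_objective(numeric(0), 0, dt), "empty")
})

test_that("bilateral switching selects exactly one active leg per sample", {
  p <- pendulum_params(4, 2.16)
  sched <- switch_schedule(data.frame(
    leg = c("right", "left"),
    t_start = c(0, 0.6), t_end = c(0.6, 1.2),
    x_p = c(0, 0.3), x_sd = c(0.3, 0.6), T_land = c(0.45, 1.05)))
  st <- list(x = 0.1, xdot = 0.3)
  before <- bilateral_mpc_zmp(st, sched, 0.59, p)
  after <- bilateral_mpc_zmp(st, sched, 0.60, p)
  expect_equal(before$leg, "right"); expect_equal(after$leg, "left")
  expect_false(isTRUE(all.equal(before$x_zmp, after$x_zmp)))

  # activations tile time: each sample maps to exactly one window
  for (t in seq(0, 1.19, by = 0.01)) {
    hit <- bilateral_mpc_zmp(st, sched, t, p)
    expect_true(hit$leg %in% c("right", "left"))
  }
  expect_error(bilateral_mpc_zmp(st, sched, 1.5, p), "not covered")
  expect_error(switch_schedule(data.frame(
    leg = c("right", "left"), t_start = c(0, 0.7), t_end = c(0.6, 1.2),
    x_p = 0, x_sd = 0, T_land = 1)), "tile")

  # a single-window schedule reduces to the unilateral law
  one <- switch_schedule(data.frame(
    leg = "right", t_start = 0, t_end = 0.6, x_p = 0, x_sd = 0.3,
    T_land = 0.6))
  expect_equal(bilateral_mpc_zmp(st, one, 0.2, p)$x_zmp,
               mpc_zmp(st, list(x_p = 0, x_sd = 0.3, T = 0.6), 0.2, p))
})
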