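test_that("natural frequency follows the inverted-pendulum scaling", {
  expect_equal(natural_frequency(9.81, 9.81), 1.0)
  expect_equal(natural_frequency(1.131), 2.945, tolerance = 1e-3)
  expect_equal(natural_frequency(0.25), 6.264, tolerance = 1e-3)
  expect_equal(natural_frequency(1.131)^2, 9.81 / 1.131, tolerance = 1e-12)
  expect_error(natural_frequency(-1), "positive")
})

test_that("COM acceleration covers the symmetric and asymmetric cases", {
  sym <- pendulum_params(3, 3)
  expect_equal(com_acceleration(list(x = 0.5, xdot = 0), 0.5, sym), 0)
  # symmetric limit kills the velocity term
  expect_equal(com_acceleration(list(x = 0.1, xdot = 5), 0, sym), 0.9)
  expect_equal(com_acceleration(list(x = 0.1, xdot = -5), 0, sym), 0.9)
  asym <- pendulum_params(4, 2.16)
  expect_equal(com_acceleration(list(x = 0.1, xdot = 0.2), 0, asym),
               8.64 * 0.1 + 1.84 * 0.2)
})

test_that("system matrix has the stated eigenstructure", {
  sym <- pendulum_params(3, 3)
  expect_equal(system_matrix(sym), matrix(c(0, 1, 9, 0), 2, byrow = TRUE))
  ev <- eigen(system_matrix(sym))$values
  expect_equal(sort(ev), c(-3, 3))

  set.seed(42)
  for (i in 1:100) {
    z1 <- runif(1, 0.5, 8); z2 <- runif(1, 0.5, 8)
    A <- system_matrix(pendulum_params(z1, z2))
    e <- eigen(A)
    expect_equal(sort(Re(e$values)), sort(c(z1, -z2)), tolerance = 1e-9)
    # eigenvector directions (1, z1) and (1, -z2)
    for (j in 1:2) {
      v <- e$vectors[, j] / e$vectors[1, j]
      expect_equal(v[2], e$values[j], tolerance = 1e-9)
    }
    # diagonalization identity: T D T^-1 equals the companion matrix
    Tm <- cbind(c(1, z1), c(1, -z2))
    expect_equal(Tm %*% diag(c(z1, -z2)) %*% solve(Tm), A, tolerance = 1e-9)
  }
})

test_that("closed-form solution matches its initial condition and an integrator", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:12) {
    p <- pendulum_params(runif(1, 1, 6), runif(1, 1, 6))
    s0 <- list(x = runif(1, -0.3, 0.3), xdot = runif(1, -0.8, 0.8))
    zm <- runif(1, -0.2, 0.2)
    at0 <- closed_form_solution(s0, zm, p, 0)
    expect_equal(at0$x, s0$x); expect_equal(at0$xdot, s0$xdot)
    for (tt in c(0.5, 2)) {
      ref <- integrate_pendulum(s0, function(t, y) zm, p, tt, dt = 5e-4)
      cf <- closed_form_solution(s0, zm, p, tt)
      expect_equal(cf$x, ref$x, tolerance = 1e-8)
      expect_equal(cf$xdot, ref$xdot, tolerance = 1e-7)
    }
  }
})

test_that("states on the stable eigendirection converge to the ZMP", {
  p <- pendulum_params(4, 2.16)
  zm <- 0.1
  # divergent coefficient vanishes when x0 - zm = -xdot0 / zeta2
  s0 <- list(x = zm - 0.5 / p$zeta2, xdot = 0.5)
  sol <- closed_form_solution(s0, zm, p, c(1, 3, 6))
  expect_true(all(abs(sol$x - zm) < abs(s0$x - zm)))
  expect_lt(abs(sol$x[3] - zm), 1e-5)
})

test_that("symmetric limit of the asymmetric formulas is exact", {
  z <- 3.2
  sym <- pendulum_params(z, z)
  s0 <- list(x = 0.12, xdot = -0.4); zm <- 0.05
  # two-exponential solution vs the cosh/sinh symmetric form
  tt <- seq(0, 1.5, by = 0.25)
  chi0 <- s0$x - zm
  x_sym <- 0.5 * (chi0 + s0$xdot / z) * exp(z * tt) +
    0.5 * (chi0 - s0$xdot / z) * exp(-z * tt) + zm
  expect_equal(closed_form_solution(s0, zm, sym, tt)$x, x_sym,
               tolerance = 1e-14)
  expect_equal(com_acceleration(s0, zm, sym), z^2 * (s0$x - zm),
               tolerance = 1e-14)
  expect_equal(system_matrix(sym), matrix(c(0, 1, z^2, 0), 2, byrow = TRUE))
})

test_that("capture point stops the COM when the ZMP is held there", {
  expect_equal(capture_point(list(x = 0.3, xdot = 0), 2.16), 0.3)
  expect_equal(capture_point(list(x = 0.1, xdot = 0.216), 2.16), 0.2)
  p <- pendulum_params(4, 2.16)
  s0 <- list(x = 0.1, xdot = 0.4)
  cp <- capture_point(s0, p$zeta2)
  sol <- closed_form_solution(s0, cp, p, c(2, 5))
  expect_lt(abs(sol$xdot[2]), 1e-4)
  expect_lt(abs(sol$x[2] - cp), 1e-4)
})

test_that("feedback gains place the closed-loop eigenvalues", {
  g <- feedback_gains(1, 1, 3)
  expect_equal(g$k1, 2); expect_equal(g$k2, 2 / 3)
  expect_equal(feedback_gains(0, 5, 2)$k1, 1)

  set.seed(3)
  for (i in 1:20) {
    q1 <- runif(1, 0.2, 3); q2 <- runif(1, 0.2, 3); z <- runif(1, 1, 6)
    gg <- feedback_gains(q1, q2, z)
    A <- matrix(c(0, 1, z^2 * (1 - gg$k1), -z^2 * gg$k2), 2, byrow = TRUE)
    expect_equal(sort(eigen(A)$values), sort(c(-z * q1, -z * q2)),
                 tolerance = 1e-8)
  }
})

test_that("state-feedback target ZMP and closed-loop convergence", {
  g <- feedback_gains(1, 1, 3, xd = 0.2)
  expect_equal(target_zmp_feedback(list(x = 0.2, xdot = 0), g), 0.2)
  g0 <- feedback_gains(1, 1, 3, xd = 0)
  expect_equal(target_zmp_feedback(list(x = 0.1, xdot = 0), g0), 0.2)

  skip_if_not_installed("deSolve")
  p <- pendulum_params(3, 3)
  zf <- function(t, y) target_zmp_feedback(list(x = y[1], xdot = y[2]), g)
  end <- integrate_pendulum(list(x = 0.35, xdot = -0.2), zf, p, 6)
  expect_equal(end$x, g$xd, tolerance = 1e-4)
  expect_equal(end$xdot, 0, tolerance = 1e-4)
})

test_that("ZMP saturation clamps and is idempotent", {
  b <- list(x_zmp_min = -0.1, x_zmp_max = 0.25)
  expect_equal(saturate_zmp(0.1, b), 0.1)
  expect_equal(saturate_zmp(0.9, b), 0.25)
  expect_equal(saturate_zmp(-3, b), -0.1)
  v <- seq(-1, 1, by = 0.05)
  expect_equal(saturate_zmp(saturate_zmp(v, b), b), saturate_zmp(v, b))
  expect_error(saturate_zmp(0, list(x_zmp_min = 1, x_zmp_max = 0)), "bounds")
})

test_that("kinematic ZMP with angular-momentum correction", {
  expect_equal(zmp_from_kinematics(c(0.3, 0, 1), c(0, 0, 0), 0, M = 57), 0.3)
  expect_equal(zmp_from_kinematics(c(0, 0, 1), c(1, 0, 0), 0, M = 57),
               -1 / 9.81, tolerance = 1e-12)
  base <- zmp_from_kinematics(c(0, 0, 1), c(1, 0, 0), 0, M = 57)
  with_L <- zmp_from_kinematics(c(0, 0, 1), c(1, 0, 0), 10, M = 57)
  expect_equal(with_L - base, -10 / (57 * 9.81), tolerance = 1e-12)
  expect_lt(angular_momentum_zmp_coefficient(57), 0)
  expect_equal(angular_momentum_zmp_coefficient(57), -1 / (57 * 9.81))
  expect_error(zmp_from_kinematics(c(0, 0, 1), c(0, 0, -20), 0, M = 57),
               "flight")
})

test_that("angular momentum about the COM sums segment cross products", {
  expect_equal(angular_momentum_about_com(matrix(0, 1, 3), matrix(c(1, 2, 3), 1), 5),
               c(0, 0, 0))
  expect_equal(angular_momentum_about_com(matrix(c(1, 0, 0), 1),
                                          matrix(c(0, 1, 0), 1), 2),
               c(0, 0, 2))
  # mirrored pair with opposite swing velocities: sagittal component cancels
  p <- rbind(c(0.2, 0.1, 0.3), c(0.2, -0.1, 0.3))
  v <- rbind(c(0.5, 0.2, -0.1), c(-0.5, 0.2, 0.1))
  L <- angular_momentum_about_com(p, v, c(2, 2))
  expect_equal(L[2], 0, tolerance = 1e-12)
  expect_error(angular_momentum_about_com(p, v, c(1, 2, 3)), "matching")
})
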