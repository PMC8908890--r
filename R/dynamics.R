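# COM-ZMP inverted-pendulum dynamics: symmetric and asymmetric eigenstructure,
# state feedback, capture point, ZMP saturation, angular-momentum-corrected ZMP.

#' Pendulum parameters
#'
#' Parameters of the COM-ZMP linear inverted pendulum with (possibly
#' asymmetric) eigenvalues. The divergent mode has eigenvalue \code{+zeta1},
#' the convergent mode \code{-zeta2}; the classic symmetric pendulum is the
#' special case \code{zeta1 == zeta2 == sqrt(g / z_com)}.
#'
#' @param zeta1 Unstable-mode eigenvalue magnitude (1/s), > 0.
#' @param zeta2 Stable-mode eigenvalue magnitude (1/s), > 0.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @param z_com Nominal COM height (m); defaults to \code{g / (zeta1*zeta2)}
#'   so that the equivalent symmetric pendulum frequency matches
#'   \code{sqrt(zeta1 * zeta2)}.
#' @return An object of class \code{pendulum_params}.
#' @export
pendulum_params <- function(zeta1, zeta2 = zeta1, g = 9.81,
                            z_com = g / (zeta1 * zeta2)) {
  stopifnot_scalar(zeta1, "zeta1"); stopifnot_scalar(zeta2, "zeta2")
  stopifnot_scalar(g, "g"); stopifnot_scalar(z_com, "z_com")
  if (zeta1 <= 0 || zeta2 <= 0) stop("eigenvalue magnitudes must be positive")
  structure(list(zeta1 = zeta1, zeta2 = zeta2, g = g, z_com = z_com),
            class = "pendulum_params")
}

#' @export
print.pendulum_params <- function(x, ...) {
  cat(sprintf("COM-ZMP pendulum: zeta1 = %.4g 1/s, zeta2 = %.4g 1/s (%s), g = %.3f, z_com = %.4g m\n",
              x$zeta1, x$zeta2,
              if (isTRUE(all.equal(x$zeta1, x$zeta2))) "symmetric" else "asymmetric",
              x$g, x$z_com))
  invisible(x)
}

#' Natural frequency of the linearized pendulum
#'
#' \code{sqrt(g / z_com)}: the eigenvalue magnitude of the symmetric
#' COM-ZMP pendulum at constant COM height.
#'
#' @param z_com COM height above the ZMP plane (m), > 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return Frequency in 1/s.
#' @export
natural_frequency <- function(z_com, g = 9.81) {
  stopifnot_scalar(z_com, "z_com")
  if (z_com <= 0) stop("`z_com` must be positive")
  sqrt(g / z_com)
}

#' Horizontal COM acceleration of the pendulum
#'
#' Asymmetric equation of motion
#' \code{xddot = zeta1*zeta2*(x - x_zmp) + (zeta1 - zeta2)*xdot}; for
#' \code{zeta1 == zeta2 == zeta} this is the symmetric
#' \code{zeta^2 * (x - x_zmp)}.
#'
#' @param state List or numeric vector with elements \code{x} (m) and
#'   \code{xdot} (m/s).
#' @param x_zmp ZMP position (m).
#' @param params A \code{pendulum_params}.
#' @return Acceleration (m/s^2).
#' @export
com_acceleration <- function(state, x_zmp, params) {
  s <- as_planar_state(state)
  params$zeta1 * params$zeta2 * (s$x - x_zmp) +
    (params$zeta1 - params$zeta2) * s$xdot
}

#' @keywords internal
#' @noRd
as_planar_state <- function(state) {
  if (is.list(state)) {
    x <- state$x; xdot <- state$xdot
  } else {
    x <- state[[1]]; xdot <- state[[2]]
  }
  if (!is.finite(x) || !is.finite(xdot)) stop("state must be finite")
  list(x = x, xdot = xdot)
}

#' System matrix of the COM-ZMP state equation
#'
#' Companion matrix \code{[[0, 1], [zeta1*zeta2, zeta1 - zeta2]]} whose
#' eigenvalues are \code{zeta1} and \code{-zeta2} with eigenvector
#' directions \code{(1, zeta1)} and \code{(1, -zeta2)}.
#'
#' @param params A \code{pendulum_params}.
#' @return 2x2 numeric matrix.
#' @export
system_matrix <- function(params) {
  matrix(c(0, 1,
           params$zeta1 * params$zeta2, params$zeta1 - params$zeta2),
         nrow = 2, byrow = TRUE)
}

#' Closed-form pendulum solution under constant ZMP
#'
#' Two-exponential general solution of the asymmetric pendulum with the ZMP
#' held at \code{x_zmp}:
#' \deqn{x(t) = A e^{\zeta_1 t} + B e^{-\zeta_2 t} + x_{zmp}}
#' with \eqn{A = (x_0 + \dot x_0/\zeta_2 - x_{zmp}) / (1 + \zeta_1/\zeta_2)}
#' and \eqn{B = (x_0 - \dot x_0/\zeta_1 - x_{zmp}) / (1 + \zeta_2/\zeta_1)};
#' the velocity is the time derivative
#' \eqn{\dot x(t) = \zeta_1 A e^{\zeta_1 t} - \zeta_2 B e^{-\zeta_2 t}}.
#'
#' @param state0 Initial state: list with \code{x}, \code{xdot}.
#' @param x_zmp Constant ZMP position (m).
#' @param params A \code{pendulum_params}.
#' @param t Time(s) since the initial state (s, >= 0); vectorized.
#' @return A list with vectors \code{x} and \code{xdot}.
#' @export
closed_form_solution <- function(state0, x_zmp, params, t) {
  s <- as_planar_state(state0)
  if (any(t < 0)) stop("`t` must be non-negative")
  z1 <- params$zeta1; z2 <- params$zeta2
  A <- (s$x + s$xdot / z2 - x_zmp) / (1 + z1 / z2)
  B <- (s$x - s$xdot / z1 - x_zmp) / (1 + z2 / z1)
  e1 <- exp(z1 * t); e2 <- exp(-z2 * t)
  list(x = A * e1 + B * e2 + x_zmp,
       xdot = z1 * A * e1 - z2 * B * e2)
}

#' Capture point
#'
#' Ground point where placing the ZMP brings the COM asymptotically to rest:
#' \code{x + xdot / zeta2}.
#'
#' @param state List with \code{x} (m) and \code{xdot} (m/s).
#' @param zeta2 Stable-mode eigenvalue magnitude (1/s), > 0.
#' @return Capture point position (m).
#' @export
capture_point <- function(state, zeta2) {
  s <- as_planar_state(state)
  stopifnot_scalar(zeta2, "zeta2")
  if (zeta2 <= 0) stop("`zeta2` must be positive")
  s$x + s$xdot / zeta2
}

#' Feedback gains placing the closed-loop eigenvalues
#'
#' Virtual spring-damper ZMP regulation gains \code{k1 = q1*q2 + 1} and
#' \code{k2 = (q1 + q2) / zeta}. Substituted into the symmetric closed-loop
#' state matrix \code{[[0, 1], [zeta^2*(1 - k1), -zeta^2*k2]]} these place
#' the eigenvalues at \code{-zeta*q1} and \code{-zeta*q2}.
#'
#' @param q1,q2 Dimensionless eigenvalue scale factors.
#' @param zeta Pendulum natural frequency (1/s), > 0.
#' @param xd COM reference position (m), default 0.
#' @return A list of class \code{feedback_gains} with \code{k1}
#'   (dimensionless), \code{k2} (s) and \code{xd} (m).
#' @export
feedback_gains <- function(q1, q2, zeta, xd = 0) {
  stopifnot_scalar(q1, "q1"); stopifnot_scalar(q2, "q2")
  stopifnot_scalar(zeta, "zeta"); stopifnot_scalar(xd, "xd")
  if (zeta <= 0) stop("`zeta` must be positive")
  structure(list(k1 = q1 * q2 + 1, k2 = (q1 + q2) / zeta, xd = xd),
            class = "feedback_gains")
}

#' Target ZMP from linear state feedback
#'
#' The commanded ZMP as a linear sum of COM position and velocity:
#' \code{k1*(x - xd) + k2*xdot + xd}.
#'
#' @param state List with \code{x}, \code{xdot}.
#' @param gains A \code{feedback_gains} (or list with \code{k1}, \code{k2},
#'   \code{xd}).
#' @return Desired ZMP (m), before support-area saturation.
#' @export
target_zmp_feedback <- function(state, gains) {
  s <- as_planar_state(state)
  gains$k1 * (s$x - gains$xd) + gains$k2 * s$xdot + gains$xd
}

#' Saturate a desired ZMP to the support bounds
#'
#' The physical ZMP is confined to the foot-support interval; the commanded
#' ZMP is clamped to \code{[x_zmp_min, x_zmp_max]}, selecting the matching
#' branch of the piecewise closed-loop dynamics.
#'
#' @param x_zmp_desired Desired ZMP (m); vectorized.
#' @param bounds List or numeric vector with \code{x_zmp_min} and
#'   \code{x_zmp_max} (m), \code{min <= max}.
#' @return Saturated ZMP (m).
#' @export
saturate_zmp <- function(x_zmp_desired, bounds) {
  if (is.list(bounds)) b <- c(bounds$x_zmp_min, bounds$x_zmp_max)
  else b <- as.numeric(bounds)
  if (length(b) != 2L || b[1] > b[2]) stop("invalid support bounds")
  pmin(pmax(x_zmp_desired, b[1]), b[2])
}

#' ZMP from whole-body kinematics with angular-momentum correction
#'
#' Moment-balance ZMP of the COM dynamics,
#' \deqn{x_{ZMP} = \frac{x (g + \ddot z) - \ddot x z}{g + \ddot z}
#'   - \frac{\dot L_{Gy}}{M (g + \ddot z)},}
#' i.e. the pendulum-model ZMP plus the rate of angular momentum about the
#' COM acting through the (negative) coefficient
#' \code{c = -1 / (M * (g + zddot))}. With \code{Ldot_y = 0} and
#' \code{zddot = 0} this reduces to \code{x - xddot * z / g}.
#'
#' @param com_pos COM position 3-vector (m).
#' @param com_acc COM acceleration 3-vector (m/s^2).
#' @param Ldot_y Sagittal-plane rate of angular momentum about the COM
#'   (kg m^2/s^2), default 0.
#' @param M Whole-body mass (kg), > 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return ZMP position along x (m).
#' @seealso [angular_momentum_zmp_coefficient()]
#' @export
zmp_from_kinematics <- function(com_pos, com_acc, Ldot_y = 0, M, g = 9.81) {
  if (length(com_pos) != 3L || length(com_acc) != 3L)
    stop("`com_pos` and `com_acc` must be 3-vectors")
  if (M <= 0) stop("`M` must be positive")
  gz <- g + com_acc[3]
  if (gz <= 0) stop("degenerate (flight) condition: g + zddot <= 0")
  (com_pos[1] * gz - com_acc[1] * com_pos[3]) / gz - Ldot_y / (M * gz)
}

#' Angular-momentum ZMP coefficient
#'
#' The constant \code{c = -1 / (M * (g + zddot))} multiplying the rate of
#' angular momentum in the corrected ZMP; negative after landing and close
#' to zero (in effect) before landing when the momentum rate itself is small.
#'
#' @inheritParams zmp_from_kinematics
#' @param zddot Vertical COM acceleration (m/s^2), default 0.
#' @return Coefficient in 1/(N).
#' @export
angular_momentum_zmp_coefficient <- function(M, g = 9.81, zddot = 0) {
  if (M <= 0) stop("`M` must be positive")
  gz <- g + zddot
  if (gz <= 0) stop("degenerate (flight) condition: g + zddot <= 0")
  -1 / (M * gz)
}

#' Angular momentum of body segments about the whole-body COM
#'
#' \code{L = sum_i p_i x (m_i v_i)} with positions expressed relative to the
#' whole-body COM.
#'
#' @param segment_coms n x 3 matrix of segment COM positions relative to the
#'   whole-body COM (m).
#' @param segment_velocities n x 3 matrix of segment COM velocities (m/s).
#' @param segment_masses Length-n vector of segment masses (kg).
#' @return Angular momentum 3-vector (kg m^2/s).
#' @export
angular_momentum_about_com <- function(segment_coms, segment_velocities,
                                       segment_masses) {
  p <- rbind(segment_coms); v <- rbind(segment_velocities)
  if (nrow(p) != nrow(v) || nrow(p) != length(segment_masses))
    stop("segment positions, velocities and masses must have matching lengths")
  L <- c(0, 0, 0)
  for (i in seq_len(nrow(p))) {
    mi_v <- segment_masses[i] * v[i, ]
    L <- L + c(p[i, 2] * mi_v[3] - p[i, 3] * mi_v[2],
               p[i, 3] * mi_v[1] - p[i, 1] * mi_v[3],
               p[i, 1] * mi_v[2] - p[i, 2] * mi_v[1])
  }
  L
}
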