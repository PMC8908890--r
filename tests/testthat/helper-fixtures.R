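# Shared fixtures: simulations are cached so the suite builds each study
# condition once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

sim_walk_clean <- function() fixture("walk_clean", function()
  simulate_walk(walk_scenario(n_steps = 6, noise = NULL)))

sim_walk_noisy <- function() fixture("walk_noisy", function()
  simulate_walk(walk_scenario(n_steps = 6, seed = 11)))

sim_stepping_clean <- function() fixture("stepping_clean", function()
  simulate_walk(walk_scenario(kind = "stepping", noise = NULL)))

sim_turn_clean <- function() fixture("turn_clean", function()
  simulate_walk(walk_scenario(kind = "turn_walk", n_steps = 8, noise = NULL)))

# adaptive/fixed-step integration of the pendulum under a ZMP policy,
# independent of the closed-form path (oracle for the analytic solution)
integrate_pendulum <- function(state0, zmp_fun, params, t_end, dt = 1e-3) {
  f <- function(t, y, parms) {
    zm <- zmp_fun(t, y)
    list(c(y[2], params$zeta1 * params$zeta2 * (y[1] - zm) +
             (params$zeta1 - params$zeta2) * y[2]))
  }
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(c(state0$x, state0$xdot), times, f, NULL, method = "rk4")
  list(x = unname(out[nrow(out), 2]), xdot = unname(out[nrow(out), 3]))
}

# nearest detected event time for a (leg, event) truth row
match_event <- function(det_events, leg, event, time) {
  d <- det_events[det_events$leg == leg & det_events$event == event, ]
  if (nrow(d) == 0L) return(NA_real_)
  d$time[which.min(abs(d$time - time))]
}
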