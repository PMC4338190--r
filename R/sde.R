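#' Configuration for a normal-form simulation
#'
#' Builds the parameter set for a stochastic normal-form path driven slowly
#' towards its bifurcation.  Two systems are supported: the saddle-node
#' normal form \deqn{dV = (-y + \rho V^2)\,dt + \sigma_1 dW,\qquad dy = -\epsilon\,dt,}
#' whose stable equilibrium \eqn{-\sqrt{y/\rho}} exists for \eqn{y > 0}, and
#' the two-component subcritical Hopf normal form
#' \deqn{dV_1 = (yV_1 - V_2 + V_1 r^2)\,dt + \sigma_1 dW_1,\quad
#'       dV_2 = (V_1 + yV_2 + V_2 r^2)\,dt + \sigma_2 dW_2,}
#' with \eqn{r^2 = V_1^2 + V_2^2}, stable at the origin for \eqn{y < 0}.
#' In both cases the control parameter drifts towards the bifurcation at
#' \eqn{y_c = 0} with speed \eqn{\epsilon}, reaching it at
#' \eqn{t_c = |y_0|/\epsilon}.  Impulsive perturbations (additive state
#' kicks of size `pulse_amplitude`) are applied every `pulse_spacing` time
#' units; for the Hopf system the kick is added to both components.
#'
#' Defaults reproduce the standard illustration of each system:
#' saddle-node with \eqn{y_0 = 1.6}, \eqn{V_0 = -4}, \eqn{\epsilon = 0.001},
#' \eqn{\rho = 0.1}, \eqn{\sigma_1 = 0.001}, kicks of 0.1 every 60 time
#' units (so \eqn{t_c = 1600}); Hopf with \eqn{y_0 = -2},
#' \eqn{\sigma_{1,2} = 0.001}, kicks of 0.005 (so \eqn{t_c = 2000}).
#'
#' The integration step `dt` defaults to 0.006 for the saddle-node system,
#' making each 60-unit inter-pulse interval hold exactly 10000 samples
#' (5000 pre-pulse statistics samples + 5000 recovery-fit samples), and to
#' 0.0032 for the Hopf system, so that the 500-sample recovery window spans
#' 1.6 time units, about a quarter of the rotation period \eqn{2\pi}; see
#' the package vignette for why the Hopf recovery window must stay well
#' inside one rotation cycle.
#'
#' @param bifurcation_kind `"saddle_node"` or `"hopf"`.
#' @param epsilon drift rate of the control parameter per unit time
#'   (\eqn{\ge 0}; 0 freezes `y`, in which case `t_end` is required).
#' @param rho quadratic coefficient of the saddle-node form (> 0).
#' @param sigma1,sigma2 white-noise amplitudes (`sigma2` only used by the
#'   second Hopf component).
#' @param pulse_amplitude additive kick applied at each pulse time.
#' @param pulse_spacing time between successive kicks; the first kick
#'   arrives at `pulse_spacing`, not at 0.
#' @param y0 initial control-parameter value (> 0 for saddle-node,
#'   < 0 for Hopf).
#' @param state0 initial state: scalar \eqn{V_0} (saddle-node) or length-2
#'   \eqn{(V_{1,0}, V_{2,0})} (Hopf).
#' @param dt integration step (> 0).
#' @param seed integer RNG seed; one seeded generator drives the whole path.
#' @param escape_bound hard cap on the state magnitude; integration also
#'   stops when the state leaves the basin of attraction (past the unstable
#'   branch \eqn{+\sqrt{y/\rho}+1} for saddle-node, radius
#'   \eqn{\max(2\sqrt{-y}, 0.5)} for Hopf), standing in for spike onset.
#' @param t_end end of integration; defaults to \eqn{t_c} when
#'   `epsilon > 0`.
#'
#' @return An object of class `sde_config` (a validated list).
#' @seealso [simulate_saddle_node()], [simulate_hopf()]
#' @export
sde_config <- function(bifurcation_kind = c("saddle_node", "hopf"),
                       epsilon = 0.001,
                       rho = 0.1,
                       sigma1 = 0.001,
                       sigma2 = 0.001,
                       pulse_amplitude = NULL,
                       pulse_spacing = 60,
                       y0 = NULL,
                       state0 = NULL,
                       dt = NULL,
                       seed = 1L,
                       escape_bound = NULL,
                       t_end = NULL) {
  bifurcation_kind <- match.arg(bifurcation_kind)
  sn <- bifurcation_kind == "saddle_node"
  if (is.null(y0)) y0 <- if (sn) 1.6 else -2
  if (is.null(state0)) state0 <- if (sn) -4 else c(0, 0)
  if (is.null(dt)) dt <- if (sn) 0.006 else 0.0032
  if (is.null(pulse_amplitude)) pulse_amplitude <- if (sn) 0.1 else 0.005
  if (is.null(escape_bound)) escape_bound <- if (sn) 50 else 10

  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(epsilon, "epsilon")
  if (epsilon < 0) csd_error("config", "`epsilon` must be >= 0")
  stopifnot_scalar(pulse_spacing, "pulse_spacing", positive = TRUE)
  stopifnot_scalar(y0, "y0")
  stopifnot_scalar(pulse_amplitude, "pulse_amplitude")
  stopifnot_scalar(escape_bound, "escape_bound", positive = TRUE)
  if (sn) {
    stopifnot_scalar(rho, "rho", positive = TRUE)
    if (y0 <= 0)
      csd_error("config", "saddle-node runs need y0 > 0 (a stable branch must exist)")
    if (length(state0) != 1L)
      csd_error("config", "saddle-node `state0` is a single value V0")
  } else {
    if (y0 >= 0)
      csd_error("config", "Hopf runs need y0 < 0 (origin must start stable)")
    if (length(state0) != 2L)
      csd_error("config", "Hopf `state0` is the pair (V1_0, V2_0)")
  }
  if (epsilon == 0 && is.null(t_end))
    csd_error("config", "`t_end` is required when epsilon = 0 (y never reaches y_c)")
  if (is.null(t_end)) t_end <- abs(y0) / epsilon
  stopifnot_scalar(t_end, "t_end", positive = TRUE)

  structure(list(
    bifurcation_kind = bifurcation_kind, epsilon = epsilon, rho = rho,
    sigma1 = sigma1, sigma2 = sigma2, pulse_amplitude = pulse_amplitude,
    pulse_spacing = pulse_spacing, y0 = y0, state0 = state0, dt = dt,
    seed = as.integer(seed), escape_bound = escape_bound, t_end = t_end
  ), class = "sde_config")
}

#' Stable equilibrium branch of the saddle-node normal form
#'
#' For \eqn{dV/dt = -y + \rho V^2} the equilibria are
#' \eqn{\pm\sqrt{y/\rho}} when \eqn{y > 0}; the lower branch
#' \eqn{-\sqrt{y/\rho}} is the stable one.
#'
#' @param y control-parameter value(s); all must be > 0.
#' @param rho quadratic coefficient (> 0).
#' @return The stable equilibrium \eqn{-\sqrt{y/\rho}}, vectorized over `y`.
#' @export
#' @examples
#' stable_branch(1.6, 0.1)  # -4
stable_branch <- function(y, rho) {
  stopifnot_scalar(rho, "rho", positive = TRUE)
  if (any(!is.finite(y)) || any(y <= 0))
    csd_error("no_equilibrium",
              "no stable equilibrium exists for y <= 0 (at or past the bifurcation)")
  -sqrt(y / rho)
}

#' Linearized recovery rate at a pre-bifurcation control value
#'
#' Analytic recovery rate of the linearization around the stable state:
#' \eqn{\lambda = 2\sqrt{\rho y}} for the saddle-node form (valid for
#' \eqn{y > 0}) and \eqn{\lambda = |y|} for the Hopf form (valid for
#' \eqn{y < 0}).  Serves as the exact oracle against which fitted
#' pulse-recovery rates are checked.
#'
#' @param y control-parameter value(s) on the stable side.
#' @param kind `"saddle_node"` or `"hopf"`, or an [sde_config()] whose kind
#'   and `rho` are used.
#' @param rho quadratic coefficient (saddle-node only).
#' @return Recovery rate(s) in inverse time units.
#' @export
linearized_recovery_rate <- function(y, kind = c("saddle_node", "hopf"), rho = 0.1) {
  if (inherits(kind, "sde_config")) {
    rho <- kind$rho
    kind <- kind$bifurcation_kind
  }
  kind <- match.arg(kind)
  if (kind == "saddle_node") {
    if (any(y <= 0))
      csd_error("no_stable_equilibrium",
                "recovery rate undefined at or past the bifurcation (y <= 0)")
    2 * sqrt(rho * y)
  } else {
    if (any(y >= 0))
      csd_error("no_stable_equilibrium",
                "recovery rate undefined at or past the bifurcation (y >= 0)")
    abs(y)
  }
}

pulse_grid <- function(config, n_samples) {
  # pulse times snapped to the integration grid; first pulse at one spacing
  if (config$t_end < config$pulse_spacing)
    return(list(idx = integer(0), times = numeric(0)))
  times <- seq(config$pulse_spacing, config$t_end, by = config$pulse_spacing)
  idx <- round(times / config$dt) + 1L
  keep <- idx >= 1L & idx <= n_samples
  list(idx = as.integer(idx[keep]), times = (idx[keep] - 1) * config$dt)
}

new_trajectory <- function(config, res, observable, extra = list()) {
  n <- length(res[[observable]])
  escape_idx <- res$escape_idx
  if (!is.na(res$bad_idx))
    csd_error("integration_failure",
              sprintf("state became non-finite at step %d (t = %.6g); reduce dt",
                      res$bad_idx, (res$bad_idx - 1) * config$dt))
  pg <- pulse_grid(config, n)
  times <- (seq_len(n) - 1) * config$dt
  y <- if (config$bifurcation_kind == "saddle_node") {
    config$y0 - config$epsilon * times
  } else {
    config$y0 + config$epsilon * times
  }
  out <- c(list(
    times = times,
    V = res[[observable]],
    y = y,
    pulse_times = pg$times,
    pulse_idx = pg$idx,
    t_c = if (config$epsilon > 0) abs(config$y0) / config$epsilon else Inf,
    escape_time = if (is.na(escape_idx)) NA_real_ else (escape_idx - 1) * config$dt,
    config = config
  ), extra)
  structure(out, class = "csd_trajectory")
}

#' Simulate a noisy saddle-node normal form with slow drift and pulses
#'
#' Integrates \eqn{dV = (-y + \rho V^2)dt + \sigma_1 dW} with
#' \eqn{y(t) = y_0 - \epsilon t} by explicit Euler-Maruyama at fixed step
#' `dt`, adding an instantaneous kick of `pulse_amplitude` every
#' `pulse_spacing` time units.  Integration stops at `t_end` or as soon as
#' the state escapes past the unstable branch (the model analogue of spike
#' onset).
#'
#' @param config an [sde_config()] with `bifurcation_kind = "saddle_node"`.
#' @return A `csd_trajectory`: uniform time grid `times`, state `V`,
#'   control-parameter series `y`, `pulse_times` (on the grid),
#'   deterministic crossing time `t_c = y0/epsilon`, `escape_time`
#'   (`NA` if the path never escaped) and the generating `config`.
#' @export
#' @examples
#' tr <- simulate_saddle_node(sde_config(seed = 7))
#' tr$t_c  # 1600
simulate_saddle_node <- function(config = sde_config()) {
  if (!inherits(config, "sde_config") ||
      config$bifurcation_kind != "saddle_node")
    csd_error("unsupported_kind", "config must be a saddle-node sde_config")
  lam0 <- 2 * sqrt(config$rho * config$y0)
  if (config$dt >= 2 / lam0)
    csd_error("unstable_dt",
              sprintf("dt = %g exceeds the explicit-Euler stability bound 2/lambda = %g",
                      config$dt, 2 / lam0))
  n_steps <- floor(config$t_end / config$dt)
  pg <- pulse_grid(config, n_steps + 1L)
  set.seed(config$seed)
  res <- sn_path_cpp(config$y0, config$state0, config$epsilon, config$rho,
                     config$sigma1, config$pulse_amplitude, pg$idx,
                     config$dt, n_steps, config$escape_bound)
  new_trajectory(config, res, "V")
}

#' Simulate a noisy subcritical Hopf normal form with slow drift and pulses
#'
#' Integrates the two-component subcritical Hopf normal form with additive
#' white noise on each component and \eqn{y(t) = y_0 + \epsilon t} rising
#' towards the bifurcation, by explicit Euler-Maruyama.  At every pulse
#' time the kick `pulse_amplitude` is added to both components.  `V1` is
#' the designated observable and is stored as `V`; the second component is
#' kept as `V2`.
#'
#' @param config an [sde_config()] with `bifurcation_kind = "hopf"`.
#' @return A `csd_trajectory`; see [simulate_saddle_node()].  If, in the
#'   noise-free deterministic check, the basin radius \eqn{\sqrt{-y}} would
#'   be exceeded well before `t_c`, a warning (not an error) is raised.
#' @export
simulate_hopf <- function(config = sde_config("hopf")) {
  if (!inherits(config, "sde_config") || config$bifurcation_kind != "hopf")
    csd_error("unsupported_kind", "config must be a Hopf sde_config")
  if (config$dt >= 2 / abs(config$y0))
    csd_error("unstable_dt",
              sprintf("dt = %g exceeds the explicit-Euler stability bound 2/|y0| = %g",
                      config$dt, 2 / abs(config$y0)))
  n_steps <- floor(config$t_end / config$dt)
  pg <- pulse_grid(config, n_steps + 1L)
  set.seed(config$seed)
  res <- hopf_path_cpp(config$y0, config$state0[1], config$state0[2],
                       config$epsilon, config$sigma1, config$sigma2,
                       config$pulse_amplitude, pg$idx, config$dt, n_steps,
                       config$escape_bound)
  tr <- new_trajectory(config, res, "V1", extra = list(V2 = res$V2))
  if (!is.na(tr$escape_time) && is.finite(tr$t_c) &&
      tr$escape_time < 0.5 * tr$t_c)
    csd_warn("early_escape",
             sprintf("path left the basin at t = %.4g, well before t_c = %.4g; noise may be too large",
                     tr$escape_time, tr$t_c))
  tr
}

#' Detrend a saddle-node trajectory along its stable equilibrium branch
#'
#' Subtracts the slowly moving stable equilibrium \eqn{-\sqrt{y(t)/\rho}}
#' from the state so that residual fluctuations and pulse-recovery
#' transients can be analyzed on a near-zero baseline.  The series is
#' truncated at the bifurcation crossing `t_c` (or at escape, whichever
#' comes first), beyond which no stable branch exists.
#'
#' @param traj a saddle-node `csd_trajectory`.
#' @return The trajectory with all series truncated to the pre-bifurcation
#'   span and an added element `Vd`, the detrended state.  Hopf
#'   trajectories are rejected: their equilibrium is the origin, so
#'   detrending is the identity and is handled by the caller.
#' @export
detrend_saddle_node <- function(traj) {
  if (!inherits(traj, "csd_trajectory") ||
      traj$config$bifurcation_kind != "saddle_node")
    csd_error("unsupported_kind",
              "detrending along the stable branch applies to saddle-node trajectories only")
  keep <- traj$times < traj$t_c & traj$y > 0
  n <- if (any(!keep)) which(!keep)[1] - 1L else length(traj$times)
  if (n < 1L) csd_error("empty_series", "no pre-bifurcation samples to detrend")
  traj$times <- traj$times[seq_len(n)]
  traj$V <- traj$V[seq_len(n)]
  traj$y <- traj$y[seq_len(n)]
  in_span <- traj$pulse_idx <= n
  traj$pulse_idx <- traj$pulse_idx[in_span]
  traj$pulse_times <- traj$pulse_times[in_span]
  traj$Vd <- traj$V - stable_branch(traj$y, traj$config$rho)
  traj
}

#' @export
print.csd_trajectory <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<csd_trajectory: %s normal form>\n", cfg$bifurcation_kind))
  cat(sprintf("  %d samples, dt = %g, span [0, %.6g]\n",
              length(x$times), cfg$dt, max(x$times)))
  cat(sprintf("  y: %.4g -> %.4g (t_c = %.6g), %d pulses every %g\n",
              x$y[1], x$y[length(x$y)], x$t_c, length(x$pulse_times),
              cfg$pulse_spacing))
  if (!is.na(x$escape_time))
    cat(sprintf("  escaped at t = %.6g\n", x$escape_time))
  if (!is.null(x$Vd)) cat("  detrended along the stable branch\n")
  invisible(x)
}
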