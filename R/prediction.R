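#' Predict the critical voltage from a truncated recovery-rate series
#'
#' Fits \eqn{\lambda = a\,(V_{cp} - V)^\theta} to the recovery rate as a
#' function of the mean pre-pulse membrane potential, with the scaling
#' exponent \eqn{\theta} held fixed and \eqn{(a, V_{cp})} free, after
#' discarding the last `n_exclude` samples before onset.  If the governing
#' bifurcation (and hence \eqn{\theta}) is known, this extrapolates the
#' tipping point from a limited window of observation using only an
#' observable of the system, without access to the control parameter.
#'
#' The optimizer is initialized at
#' \eqn{V_{cp,0} = V_{last} + 2 (V_{last} - V_{first})/n} with the
#' prefactor matched to the first sample, and \eqn{V_{cp}} is constrained
#' to `(max(V), max(V) + 50)` so the predicted threshold lies above every
#' voltage used in the fit.
#'
#' @param series a `marker_series` (its samples must approach the
#'   threshold monotonically in trend, as under a depolarizing ramp).
#' @param theta fixed scaling exponent (> 0): 0.5 for a saddle-node,
#'   1.0 for a Hopf bifurcation.
#' @param n_exclude number of final pre-onset samples withheld from the
#'   fit (default 5).
#' @return A list of class `tipping_prediction`: `V_cp` (predicted
#'   critical voltage), `prefactor_a`, `theta_used`, `V_last` (last
#'   voltage included), `delta_V_p = V_cp - V_last`,
#'   `delta_V_m = V_cm - V_last` (`NA` when the series has no measured
#'   `V_cm`), `n_excluded`, `fit_r_squared`, `n_points`.
#' @export
predict_critical_voltage <- function(series, theta = 0.5, n_exclude = 5L) {
  if (!inherits(series, "marker_series"))
    csd_error("config", "`series` must be a marker_series")
  stopifnot_scalar(theta, "theta", positive = TRUE)
  s <- series$samples[order(series$samples$pulse_time), ]
  s <- s[is.finite(s$lambda) & s$lambda > 0 & is.finite(s$mean_voltage), ]
  n_exclude <- as.integer(n_exclude)
  if (n_exclude > 0L && nrow(s) > n_exclude)
    s <- s[seq_len(nrow(s) - n_exclude), ]
  if (nrow(s) < 5L)
    csd_error("insufficient_data",
              sprintf("only %d usable samples after excluding the last %d (need 5)",
                      nrow(s), n_exclude))
  V <- s$mean_voltage
  lam <- s$lambda
  n <- length(V)
  V_last <- V[n]
  V_max <- max(V)
  vcp0 <- V_last + max(2 * (V_last - V[1]) / n, 1e-3)
  vcp0 <- max(vcp0, V_max + 1e-3)
  a0 <- lam[1] / (vcp0 - V[1])^theta
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      lam ~ a * (vcp - V)^theta,
      start = list(a = a0, vcp = vcp0),
      lower = c(1e-12, V_max + 1e-9),
      upper = c(Inf, V_last + 50),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )),
    error = function(e) NULL
  )
  if (is.null(fit))
    csd_error("prediction_failed", "critical-voltage fit did not converge")
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lam - mean(lam))^2)
  V_cm <- series$V_cm
  structure(list(
    V_cp = unname(co["vcp"]), prefactor_a = unname(co["a"]),
    theta_used = theta, V_last = V_last,
    delta_V_p = unname(co["vcp"]) - V_last,
    delta_V_m = if (is.null(V_cm) || is.na(V_cm)) NA_real_ else V_cm - V_last,
    n_excluded = n_exclude,
    fit_r_squared = 1 - ss_res / ss_tot,
    n_points = n
  ), class = "tipping_prediction")
}

#' @export
print.tipping_prediction <- function(x, ...) {
  cat(sprintf("<tipping_prediction: V_cp = %.4g (theta = %g, %d points, R^2 = %.3f)>\n",
              x$V_cp, x$theta_used, x$n_points, x$fit_r_squared))
  cat(sprintf("  delta_V_p = %.4g, delta_V_m = %.4g\n", x$delta_V_p, x$delta_V_m))
  invisible(x)
}

#' Correlate predicted and measured distances to threshold across trials
#'
#' Ordinary linear regression of the predicted distance
#' \eqn{\Delta V_p = V_{cp} - V_{last}} on the measured distance
#' \eqn{\Delta V_m = V_{cm} - V_{last}} across trials.  A significant
#' positive correlation indicates that the scaling exponent used for the
#' per-trial fits captures the true approach to threshold.
#'
#' @param predictions a list of `tipping_prediction` objects (>= 3 with
#'   both distances present).
#' @return A list of class `prediction_correlation`: `r` (Pearson),
#'   `p_value` (two-sided, on the regression slope), `slope`,
#'   `intercept`, `n_trials`, `theta_used`.
#' @export
correlate_predictions <- function(predictions) {
  dvp <- vapply(predictions, function(p) p$delta_V_p, numeric(1))
  dvm <- vapply(predictions, function(p) p$delta_V_m, numeric(1))
  theta <- unique(vapply(predictions, function(p) p$theta_used, numeric(1)))
  ok <- is.finite(dvp) & is.finite(dvm)
  if (sum(ok) < 3L)
    csd_error("insufficient_data",
              "need at least 3 trials with both delta_V_p and delta_V_m")
  dvp <- dvp[ok]; dvm <- dvm[ok]
  if (stats::sd(dvm) == 0 || stats::sd(dvp) == 0)
    csd_error("undefined_correlation",
              "zero variance across trials; correlation undefined")
  fit <- stats::lm(dvp ~ dvm)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    r = unname(stats::cor(dvp, dvm)),
    p_value = unname(sm$coefficients[2, 4]),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_trials = sum(ok),
    theta_used = if (length(theta) == 1L) theta else NA_real_
  ), class = "prediction_correlation")
}

#' @export
print.prediction_correlation <- function(x, ...) {
  cat(sprintf("<prediction_correlation: r = %.3f, p = %.3g (n = %d, theta = %g)>\n",
              x$r, x$p_value, x$n_trials, x$theta_used))
  invisible(x)
}
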