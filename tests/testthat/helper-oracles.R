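# Shared fixtures: everything is generated in code at test time.

# Ornstein-Uhlenbeck path by explicit Euler, the independent oracle for
# stationary-variance and recovery-rate checks.
ou_path <- function(lambda, sigma, dt, n, x0 = 0, kick_at = NULL, kick = 0) {
  x <- numeric(n)
  x[1] <- x0
  noise <- stats::rnorm(n - 1, 0, sigma * sqrt(dt))
  for (k in 1:(n - 1)) {
    x[k + 1] <- x[k] * (1 - lambda * dt) + noise[k]
    if (!is.null(kick_at) && (k + 1) %in% kick_at) x[k + 1] <- x[k + 1] + kick
  }
  x
}

# Minimal marker_series carrying only what the prediction fit needs.
synthetic_lambda_series <- function(V, lambda, V_cm = NA_real_) {
  structure(list(
    samples = data.frame(
      pulse_time = seq_along(V), delta_I = rev(seq_along(V)),
      lambda = lambda, r_squared = 0.99, converged = TRUE,
      variance = 1, acf = 0.5, mean_voltage = V
    ),
    I_c = NA_real_, V_cm = V_cm, onset_time = NA_real_,
    acf_lag = 100L, acf_lag_time = 0.6, units = "physical",
    kind = "saddle_node", n_dropped = 0L
  ), class = "marker_series")
}

# Minimal marker_series with prescribed marker columns for power-law fits.
synthetic_marker_series <- function(delta_I, lambda = NULL, variance = NULL,
                                    acf = NULL) {
  n <- length(delta_I)
  structure(list(
    samples = data.frame(
      pulse_time = seq_len(n), delta_I = delta_I,
      lambda = lambda %||% rep(1, n), r_squared = 0.99,
      converged = TRUE, variance = variance %||% rep(1, n),
      acf = acf %||% rep(0.5, n), mean_voltage = -60
    ),
    I_c = NA_real_, V_cm = NA_real_, onset_time = NA_real_,
    acf_lag = 100L, acf_lag_time = 0.6, units = "model",
    kind = "saddle_node", n_dropped = 0L
  ), class = "marker_series")
}

fake_estimate <- function(marker, mean_exponent) {
  structure(list(
    marker = marker,
    symbol = c(lambda = "theta", variance = "tau", acf = "kappa")[[marker]],
    mean_exponent = mean_exponent, sd_exponent = 0.01,
    per_cutoff = data.frame(delta_I_min = 0.1, exponent = mean_exponent,
                            intercept = 0, r_squared = 0.9, n_points = 20,
                            accepted = TRUE),
    grid = 0.1, n_accepted = 1L
  ), class = "exponent_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
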