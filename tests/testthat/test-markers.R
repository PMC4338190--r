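test_that("exponential recovery fit is exact on noiseless decays", {
  tt_rate <- 1000
  for (lam in c(0.5, 2, 10, 50)) {  # 100x range
    tt <- seq(0, 0.2, by = 1 / tt_rate)
    seg <- 3 * exp(-lam * tt) + 1
    fit <- fit_recovery(seg, tt_rate)
    expect_true(fit$converged)
    expect_equal(fit$lambda, lam, tolerance = 1e-6)
  }
  tt <- seq(0, 0.2, by = 1e-3)
  fit <- fit_recovery(3 * exp(-2 * tt) + 1, 1000)
  expect_equal(fit$lambda, 2, tolerance = 1e-6)
  expect_equal(fit$a, 3, tolerance = 1e-5)
  # b is reported relative to the subtracted segment mean
  expect_equal(fit$b + mean(3 * exp(-2 * tt) + 1), 1, tolerance = 1e-5)
})

test_that("recovery fit degrades gracefully on structureless input", {
  set.seed(7)
  fit <- fit_recovery(rnorm(500), 1000)
  expect_true(!isTRUE(fit$converged) || fit$r_squared < 0.1)
  expect_error(fit_recovery(rep(1, 100), 1000), class = "csd_degenerate_fit")
  expect_error(fit_recovery(1:5, 1000), class = "csd_insufficient_data")
})

test_that("recovery fit tracks a prescribed rate on OU surrogates", {
  # lambda * window >= 1 regime; 10% tracking
  dt <- 0.006
  for (lam in c(1, 0.5, 0.2)) {
    set.seed(round(100 * lam))
    x <- ou_path(lam, sigma = 0.001, dt = dt, n = 20000,
                 kick_at = 10000, kick = 0.1)
    fit <- fit_recovery(x[10000:14999], 1 / dt)
    expect_equal(fit$lambda, lam, tolerance = 0.1)
  }
})

test_that("segment variance uses the population convention and its invariances", {
  expect_equal(segment_variance(rep(3.2, 10)), 0)
  expect_equal(segment_variance(rep(c(1, -1), 25)), 1)
  set.seed(1)
  x <- rnorm(200)
  expect_equal(segment_variance(x + 17.3), segment_variance(x))
  expect_equal(segment_variance(3 * x), 9 * segment_variance(x))
  expect_error(segment_variance(1), class = "csd_insufficient_data")
})

test_that("autocorrelation is lag-1 normalized and matches the AR(1) oracle", {
  set.seed(42)
  for (i in 1:5) {
    seg <- cumsum(rnorm(200))
    expect_equal(autocorrelation(seg, 1), 1)
  }
  # AR(1) with coefficient 0.9: ACF*(s)/ACF*(1) -> 0.9^(s-1)
  set.seed(9)
  x <- as.numeric(stats::filter(rnorm(50000), 0.9, method = "recursive"))
  expect_equal(autocorrelation(x, 10), 0.9^9, tolerance = 0.05)
  # invariance under shift and scale
  expect_equal(autocorrelation(5 * x + 3, 10), autocorrelation(x, 10))
  expect_error(autocorrelation(rep(1, 100), 5), class = "csd_undefined_acf")
  expect_error(autocorrelation(rnorm(20), 15), class = "csd_config")
})

test_that("perturbation windows tile the saddle-node trajectory correctly", {
  tr <- detrend_saddle_node(simulate_saddle_node(sde_config(seed = 5)))
  ev <- locate_perturbations(tr)
  # one event per 60-unit interval before t_c
  expect_equal(nrow(ev), 26)
  expect_equal(diff(ev$pulse_time), rep(60, 25))
  expect_true(all(ev$pre_end == ev$pulse_idx - 1))
  expect_true(all(ev$post_start == ev$pulse_idx))
  expect_true(all(ev$pre_end - ev$pre_start + 1 == 5000))
  expect_true(all(ev$post_end - ev$post_start + 1 == 5000))
  # windows never overlap each other
  spans <- cbind(c(ev$pre_start, ev$post_start), c(ev$pre_end, ev$post_end))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
})

test_that("Hopf trajectories use the short recovery window", {
  h <- simulate_hopf(sde_config("hopf", seed = 5))
  ev <- locate_perturbations(h)
  expect_true(all(ev$post_end - ev$post_start + 1 == 500))
  expect_true(all(ev$pre_end - ev$pre_start + 1 == 5000))
})

test_that("onset detection finds the first upward threshold crossing", {
  rec <- structure(list(voltage = rep(-70, 20000), v_hz = 25000,
                        current = rep(100, 2000), i_hz = 2500,
                        pulse_times = numeric(0), onset_time = NA_real_,
                        provenance = NULL), class = "csd_recording")
  rec$voltage[5000] <- -40
  expect_true(is.na(detect_onset(rec)))  # peaks below threshold
  rec$voltage[10000] <- 30
  expect_equal(detect_onset(rec), (10000 - 1) / 25000)
})

test_that("critical current averages the second before onset", {
  rec <- structure(list(voltage = rep(-70, 50000), v_hz = 25000,
                        current = rep(100, 5000), i_hz = 2500,
                        pulse_times = numeric(0), onset_time = NA_real_,
                        provenance = NULL), class = "csd_recording")
  expect_equal(critical_current(rec, 1.5), 100)
  # staircase stepping inside the averaging window: duration-weighted oracle
  rec$current <- rep(c(100, 103), each = 2500)
  onset <- 1.4
  ti <- (seq_along(rec$current) - 1) / 2500
  oracle <- mean(rec$current[ti >= onset - 1 & ti < onset])
  expect_equal(critical_current(rec, onset), oracle)
  expect_equal(oracle, 100 * (0.6 / 1) + 103 * (0.4 / 1))
  expect_error(critical_current(rec, 0.5), class = "csd_insufficient_baseline")
})

test_that("marker series trends reflect critical slowing down", {
  rho_l <- rho_v <- numeric(3)
  for (s in 1:3) {
    m <- compute_markers(simulate_saddle_node(sde_config(seed = s)))
    ok <- is.finite(m$samples$lambda)
    rho_l[s] <- cor(m$samples$pulse_time[ok], m$samples$lambda[ok],
                    method = "spearman")
    rho_v[s] <- cor(m$samples$pulse_time, m$samples$variance,
                    method = "spearman")
  }
  expect_lt(median(rho_l), -0.8)
  # variance estimates from 5000-sample windows carry ~25% sampling noise,
  # so their rank ordering is noisier than the recovery rate's
  expect_gt(median(rho_v), 0.6)
})

test_that("empty event sets are rejected", {
  tr <- simulate_saddle_node(sde_config(seed = 1, t_end = 200))
  empty <- structure(data.frame(pulse_time = numeric(0),
                                pulse_idx = integer(0),
                                pre_start = integer(0), pre_end = integer(0),
                                post_start = integer(0), post_end = integer(0)),
                     class = c("csd_events", "data.frame"), n_dropped = 0L)
  expect_error(compute_markers(tr, events = empty), class = "csd_empty_series")
  # a trajectory too short to hold any pulse has no events at all
  expect_error(locate_perturbations(simulate_saddle_node(
    sde_config(seed = 1, t_end = 50))), class = "csd_empty_series")
})

test_that("non-converged recovery fits keep their event with missing lambda", {
  m <- compute_markers(simulate_saddle_node(sde_config(seed = 2)))
  expect_true(all(c("lambda", "variance", "acf") %in% names(m$samples)))
  expect_true(all(is.finite(m$samples$variance)))
  expect_true(all(is.finite(m$samples$acf)))
  bad <- !m$samples$converged
  if (any(bad)) expect_true(all(is.na(m$samples$lambda[bad])))
})
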