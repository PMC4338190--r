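test_that("stable branch returns the lower equilibrium and rejects y <= 0", {
  expect_equal(stable_branch(1.6, 0.1), -4)
  expect_equal(stable_branch(0.4, 0.1), -2)
  expect_equal(stable_branch(c(1.6, 0.4), 0.1), c(-4, -2))
  expect_error(stable_branch(0, 0.1), class = "csd_no_equilibrium")
  expect_error(stable_branch(-1, 0.1), class = "csd_no_equilibrium")
})

test_that("linearized recovery rate matches the analytic eigenvalues", {
  expect_equal(linearized_recovery_rate(1.6, "saddle_node", rho = 0.1), 0.8)
  expect_equal(linearized_recovery_rate(-2, "hopf"), 2)
  expect_error(linearized_recovery_rate(0, "saddle_node"),
               class = "csd_no_stable_equilibrium")
  expect_error(linearized_recovery_rate(0.5, "hopf"),
               class = "csd_no_stable_equilibrium")
  cfg <- sde_config("hopf")
  expect_equal(linearized_recovery_rate(-0.7, cfg), 0.7)
})

test_that("deterministic crossing time is (y0 - y_c)/epsilon for both systems", {
  expect_equal(simulate_saddle_node(sde_config())$t_c, 1600)
  expect_equal(simulate_hopf(sde_config("hopf"))$t_c, 2000)
  for (y0 in c(0.5, 1.2)) for (eps in c(2e-3, 5e-3)) {
    tr <- simulate_saddle_node(sde_config(y0 = y0, epsilon = eps, seed = 1))
    expect_identical(tr$t_c, y0 / eps)
  }
})

test_that("control parameter follows its linear drift exactly on the grid", {
  tr <- simulate_saddle_node(sde_config(y0 = 0.9, epsilon = 0.002, seed = 2,
                                        t_end = 300))
  expect_identical(max(abs(tr$y - (0.9 - 0.002 * tr$times))), 0)
  h <- simulate_hopf(sde_config("hopf", y0 = -1, epsilon = 0.002, seed = 2,
                                t_end = 300))
  expect_identical(max(abs(h$y - (-1 + 0.002 * h$times))), 0)
  # pulse times lie on the grid
  expect_true(all(tr$pulse_times %in% tr$times))
})

test_that("zero-noise paths converge to the analytic equilibrium", {
  cfg <- sde_config(sigma1 = 0, pulse_amplitude = 0, epsilon = 0, y0 = 1,
                    state0 = -3, t_end = 100, seed = 1)
  tr <- simulate_saddle_node(cfg)
  lam <- linearized_recovery_rate(1, "saddle_node", rho = 0.1)
  after <- tr$times >= 20 / lam
  expect_lt(max(abs(tr$V[after] - (-sqrt(1 / 0.1)))), 1e-8)

  cfgh <- sde_config("hopf", sigma1 = 0, sigma2 = 0, pulse_amplitude = 0,
                     epsilon = 0, y0 = -1, state0 = c(0.1, 0), t_end = 40,
                     seed = 1)
  h <- simulate_hopf(cfgh)
  afterh <- h$times >= 20
  expect_lt(max(sqrt(h$V[afterh]^2 + h$V2[afterh]^2)), 1e-8)
  # envelope decays like exp(-t): radius at t = 5 within a few percent
  i5 <- which.min(abs(h$times - 5))
  expect_equal(sqrt(h$V[i5]^2 + h$V2[i5]^2), 0.1 * exp(-5), tolerance = 0.05)
})

test_that("identical config and seed give bit-identical trajectories", {
  cfg <- sde_config(seed = 11, t_end = 300)
  a <- simulate_saddle_node(cfg)
  b <- simulate_saddle_node(cfg)
  expect_identical(a$V, b$V)
  c <- simulate_saddle_node(sde_config(seed = 12, t_end = 300))
  expect_false(identical(a$V, c$V))
  ha <- simulate_hopf(sde_config("hopf", seed = 11, t_end = 300))
  hb <- simulate_hopf(sde_config("hopf", seed = 11, t_end = 300))
  expect_identical(ha$V, hb$V)
})

test_that("configuration invariants and stability guards are enforced", {
  expect_error(sde_config(y0 = -1), class = "csd_config")
  expect_error(sde_config("hopf", y0 = 1), class = "csd_config")
  expect_error(sde_config(dt = 0), class = "csd_config")
  expect_error(sde_config(epsilon = 0), class = "csd_config")  # needs t_end
  expect_error(sde_config(rho = -0.1), class = "csd_config")
  expect_error(simulate_saddle_node(sde_config(y0 = 100, dt = 0.6, t_end = 10)),
               class = "csd_unstable_dt")
  expect_error(simulate_hopf(sde_config("hopf", y0 = -100, dt = 0.1, t_end = 10)),
               class = "csd_unstable_dt")
})

test_that("strong noise near the basin edge raises the early-escape warning", {
  cfg <- sde_config("hopf", y0 = -0.04, epsilon = 1e-5, sigma1 = 0.05,
                    sigma2 = 0.05, pulse_amplitude = 0, seed = 4)
  expect_warning(simulate_hopf(cfg), class = "csd_early_escape")
})

test_that("detrending subtracts the stable branch and truncates at t_c", {
  # quasi-static noiseless path hugs the branch: detrended series near zero
  cfg <- sde_config(sigma1 = 0, pulse_amplitude = 0, seed = 1)
  tr <- detrend_saddle_node(simulate_saddle_node(cfg))
  far <- tr$times < 0.9 * tr$t_c
  expect_lt(max(abs(tr$Vd[far])), 0.02)
  expect_true(all(tr$times < tr$t_c))
  expect_error(detrend_saddle_node(simulate_hopf(sde_config("hopf", t_end = 50))),
               class = "csd_unsupported_kind")
})

test_that("pulse decay on a frozen noiseless path matches the linearization", {
  # single small kick at frozen y = 1: decay rate 2*sqrt(rho*y) within 2%
  cfg <- sde_config(sigma1 = 0, epsilon = 0, y0 = 1, state0 = -sqrt(10),
                    pulse_amplitude = 0.1, pulse_spacing = 50, t_end = 99,
                    seed = 1)
  tr <- simulate_saddle_node(cfg)
  i0 <- tr$pulse_idx[1]
  seg <- tr$V[i0:(i0 + 4999)] - (-sqrt(10))
  fit <- fit_recovery(seg, 1 / cfg$dt)
  expect_true(fit$converged)
  expect_equal(fit$lambda, 2 * sqrt(0.1), tolerance = 0.02)
})

test_that("stationary variance at frozen y matches sigma^2/(2 lambda)", {
  lam <- 2 * sqrt(0.1 * 1)
  target <- 0.001^2 / (2 * lam)
  v <- vapply(1:20, function(s) {
    cfg <- sde_config(sigma1 = 0.001, epsilon = 0, y0 = 1, state0 = -sqrt(10),
                      pulse_amplitude = 0, t_end = 1500, seed = s)
    tr <- simulate_saddle_node(cfg)
    keep <- tr$times > 50  # discard the transient
    mean((tr$V[keep] - mean(tr$V[keep]))^2)
  }, numeric(1))
  expect_equal(mean(v), target, tolerance = 0.1)
})
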