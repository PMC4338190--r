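test_that("critical-voltage fit is exact on correctly specified data", {
  V <- seq(-70, -55, by = 1)
  s <- synthetic_lambda_series(V, lambda = 2 * (-50 - V)^0.5, V_cm = -50)
  p <- predict_critical_voltage(s, theta = 0.5, n_exclude = 0)
  expect_equal(p$V_cp, -50, tolerance = 1e-6)
  expect_equal(p$prefactor_a, 2, tolerance = 1e-5)
  set.seed(8)
  for (i in 1:4) {
    th <- sample(c(0.3, 0.5, 1, 2), 1)
    vc <- runif(1, -52, -40)
    s <- synthetic_lambda_series(V, lambda = 1.5 * (vc - V)^th)
    p <- predict_critical_voltage(s, theta = th, n_exclude = 0)
    expect_equal(p$V_cp, vc, tolerance = 1e-6)
  }
})

test_that("a misspecified exponent biases the predicted threshold", {
  V <- seq(-70, -55, by = 1)
  s <- synthetic_lambda_series(V, lambda = 2 * (-50 - V)^0.5, V_cm = -50)
  p <- predict_critical_voltage(s, theta = 1.0, n_exclude = 0)
  expect_gt(abs(p$V_cp - (-50)), 1)
})

test_that("prediction is translation-equivariant", {
  V <- seq(-70, -56, by = 0.5)
  set.seed(2)
  lam <- 2 * (-50 - V)^0.5 * exp(rnorm(length(V), 0, 0.05))
  s0 <- synthetic_lambda_series(V, lam, V_cm = -50)
  p0 <- predict_critical_voltage(s0, 0.5)
  for (shift in c(-12.5, 7)) {
    s1 <- synthetic_lambda_series(V + shift, lam, V_cm = -50 + shift)
    p1 <- predict_critical_voltage(s1, 0.5)
    expect_equal(p1$V_cp, p0$V_cp + shift, tolerance = 1e-6)
    expect_equal(p1$delta_V_p, p0$delta_V_p, tolerance = 1e-6)
    expect_equal(p1$delta_V_m, p0$delta_V_m, tolerance = 1e-6)
  }
})

test_that("withholding fewer near-threshold points improves the prediction", {
  V <- seq(-70, -51, by = 0.5)
  set.seed(31)
  err <- sapply(c(10, 5, 0), function(nex) {
    median(sapply(1:40, function(s) {
      lam <- 2 * (-50 - V)^0.5 * exp(rnorm(length(V), 0, 0.15))
      p <- predict_critical_voltage(synthetic_lambda_series(V, lam), 0.5,
                                    n_exclude = nex)
      abs(p$V_cp + 50)
    }))
  })
  expect_true(err[3] <= err[2])
  expect_true(err[2] <= err[1])
})

test_that("prediction failure modes raise classed conditions", {
  V <- seq(-70, -55, by = 1)
  s <- synthetic_lambda_series(V, lambda = 2 * (-50 - V)^0.5)
  expect_error(predict_critical_voltage(s, theta = 0.5, n_exclude = 14),
               class = "csd_insufficient_data")
  expect_error(predict_critical_voltage(s, theta = -1),
               class = "csd_config")
  p <- predict_critical_voltage(s, 0.5, n_exclude = 0)
  expect_true(is.na(p$delta_V_m))  # no measured threshold in the series
})

test_that("cross-trial regression recovers perfect agreement", {
  preds <- lapply(1:10, function(i) {
    structure(list(delta_V_p = i / 2, delta_V_m = i / 2, theta_used = 0.5),
              class = "tipping_prediction")
  })
  cc <- correlate_predictions(preds)
  expect_equal(cc$r, 1)
  expect_equal(cc$slope, 1)
  expect_equal(cc$n_trials, 10)
  expect_lt(cc$p_value, 1e-8)
})

test_that("regression rejects degenerate or tiny inputs", {
  same <- lapply(1:5, function(i) {
    structure(list(delta_V_p = i, delta_V_m = 2, theta_used = 0.5),
              class = "tipping_prediction")
  })
  expect_error(correlate_predictions(same), class = "csd_undefined_correlation")
  two <- lapply(1:2, function(i) {
    structure(list(delta_V_p = i, delta_V_m = i, theta_used = 0.5),
              class = "tipping_prediction")
  })
  expect_error(correlate_predictions(two), class = "csd_insufficient_data")
})

test_that("regression p-values are calibrated under the null", {
  set.seed(99)
  hits <- mean(replicate(400, {
    preds <- lapply(1:20, function(i) {
      structure(list(delta_V_p = rnorm(1), delta_V_m = rnorm(1),
                     theta_used = 0.5), class = "tipping_prediction")
    })
    correlate_predictions(preds)$p_value < 0.05
  }))
  expect_gt(hits, 0.017)
  expect_lt(hits, 0.083)
})
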