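test_that("relaxation modulus is axial stress over hold strain", {
  tt <- 0:100
  sig <- 0.744 * exp(-tt / 87.866)
  series <- group_stress_series(tt, cbind(sig, 0, 0, 0, 0, 0), axis = "x")
  tr <- relaxation_modulus(series, hold_strain = 0.8)
  expect_s3_class(tr, "relaxation_trace")
  expect_equal(tr$modulus, 0.930 * exp(-tt / 87.866))
  expect_equal(attr(tr, "hold_strain"), 0.8)
  # zero stress -> zero modulus
  z <- group_stress_series(tt, matrix(0, 101, 6))
  expect_equal(relaxation_modulus(z, 0.8)$modulus, rep(0, 101))
  expect_error(relaxation_modulus(series, 0), "> 0")
})

test_that("loading-phase samples are excluded and time re-zeroed", {
  tt <- 0:50
  sig <- c(seq(0, 0.744, length.out = 11), 0.744 * exp(-(1:40) / 20))
  series <- group_stress_series(tt, cbind(sig, 0, 0, 0, 0, 0))
  tr <- relaxation_modulus(series, 0.8, hold_start = 10)
  expect_equal(tr$time, 0:40)
  expect_equal(tr$modulus[1], 0.744 / 0.8)
})

test_that("modulus from generated frames matches the prescription", {
  tgt <- 0.744
  hist <- lapply(0:4, function(k) c(tgt * exp(-k / 2), 0, 0, 0, 0, 0))
  frames <- generate_frames(8, 16, hist, seed = 31)
  series <- extract_group_stress(frames, 1:8, dt_ps = 1)
  tr <- relaxation_modulus(series, 0.8)
  want <- vapply(hist, `[`, numeric(1), 1) / 0.8
  expect_lt(max(abs(tr$modulus - want)), 1e-6 * max(want))
})

test_that("noiseless traces are recovered to 1e-3 relative", {
  for (m in list(model_rate1e8(), model_rate1e9())) {
    tr <- generate_relaxation_trace(m, duration = 1000, dt = 1)
    fit <- prony_fit(tr, restarts = 2, seed = 1, select = FALSE)
    expect_lt(abs(fit$model$moduli - m$moduli) / m$moduli, 1e-3)
    expect_lt(abs(fit$model$tau - m$tau) / m$tau, 1e-3)
    if (m$long_term > 0)
      expect_lt(abs(fit$model$long_term - m$long_term) / m$long_term, 1e-3)
    else
      expect_lt(fit$model$long_term, 1e-3 * predict(m, 0))
  }
})

test_that("a constant trace degenerates to the long-term modulus alone", {
  tr <- relaxation_trace(0:100, rep(0.5, 101), 0.8)
  fit <- prony_fit(tr, seed = 1)
  expect_equal(fit$model$long_term, 0.5, tolerance = 1e-3)
  expect_lt(fit$model$moduli, 0.01 * 0.5)
})

test_that("a pure exponential selects the two-parameter form", {
  tr <- generate_relaxation_trace(model_rate1e9(), duration = 1000, dt = 1)
  fit <- prony_fit(tr, seed = 1)
  expect_equal(fit$selected_form, "two_parameter")
  expect_identical(fit$model$long_term, 0)
  expect_lt(abs(fit$model$moduli - 2) / 2, 1e-3)
  expect_lt(abs(fit$model$tau - 100) / 100, 1e-3)
})

test_that("a clear long-term modulus keeps the three-parameter form", {
  tr <- generate_relaxation_trace(model_rate1e8(), duration = 1000, dt = 1)
  fit <- prony_fit(tr, seed = 1)
  expect_equal(fit$selected_form, "three_parameter")
})

test_that("form selection thresholds on the fraction of E(0)", {
  # long-term modulus at 1e-4 of E(0): called two-parameter at threshold 0.01
  m <- prony_model(1e-4 * 2, 2, 100)
  tr <- generate_relaxation_trace(m, duration = 1000, dt = 1)
  fit <- prony_fit(tr, seed = 1, select = FALSE, restarts = 2)
  expect_equal(select_form(fit, 0.01)$selected_form, "two_parameter")
  # the same fit at a much tighter threshold keeps three-parameter
  expect_equal(select_form(fit, 1e-6)$selected_form, "three_parameter")
})

test_that("the returned objective is the best across restarts", {
  tr <- generate_relaxation_trace(model_rate1e8(), noise_sd = 0.05, seed = 3)
  fit <- prony_fit(tr, restarts = 6, seed = 3, select = FALSE)
  expect_equal(fit$n_restarts_used, 6L)
  expect_true(all(fit$objective <= fit$restart_objectives + 1e-12))
})

test_that("noisy traces recover tau within 10% in the median", {
  taus <- vapply(1:40, function(s) {
    tr <- generate_relaxation_trace(model_rate1e8(), duration = 1000, dt = 1,
                                    noise_sd = 0.05, seed = 7000 + s)
    prony_fit(tr, restarts = 4, seed = s, select = FALSE)$model$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 87.866) / 87.866, 0.10)
})

test_that("multi-branch fits reduce to the branches present", {
  m <- prony_model(0.1, c(0.4, 0.8), c(10, 200))
  tr <- generate_relaxation_trace(m, duration = 1000, dt = 1)
  fit <- prony_fit(tr, n_branches = 2, restarts = 4, seed = 2, select = FALSE)
  expect_lt(max(abs(fit$model$tau - m$tau) / m$tau), 0.02)
  expect_lt(max(abs(fit$model$moduli - m$moduli) / m$moduli), 0.02)
})

test_that("fit object supports the standard model methods", {
  tr <- generate_relaxation_trace(model_rate1e8(), noise_sd = 0.02, seed = 9)
  fit <- prony_fit(tr, restarts = 2, seed = 9)
  expect_named(coef(fit), c("E1", "E2", "tau"))
  expect_length(predict(fit), nrow(tr))
  expect_equal(predict(fit, 0), sum(coef(fit)[c("E1", "E2")]),
               ignore_attr = TRUE)
  expect_equal(residuals(fit), tr$modulus - fitted(fit))
  s <- summary(fit)
  expect_lt(s$residual_rms, 0.05)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), nrow(tr))
  # plot renders without error
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("fitting rejects traces shorter than the parameter budget", {
  tr <- relaxation_trace(0:5, exp(-(0:5)), 0.8)
  expect_error(prony_fit(tr), "too short")
})
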