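# Assay kinetics: slope fitting, specific-activity conversion, malachite
# branch, fold stimulation and titration fits.

test_that("linear rate fitting recovers exact and noisy slopes", {
  t <- seq(0, 3600, by = 30)
  exact <- data.frame(time_s = t, a340 = 1 - 1e-5 * t)
  expect_equal(fit_linear_rate(exact)$slope, -1e-5, tolerance = 1e-12)
  flat <- data.frame(time_s = t, a340 = rep(0.8, length(t)))
  expect_equal(fit_linear_rate(flat)$slope, 0, tolerance = 1e-15)
  # noisy synthetic trace: slope within 3 SE of the generator slope
  spec <- coupled_assay_spec(true_turnover = 10, noise_sd = 0.002, seed = 8)
  fit <- fit_linear_rate(gen_coupled_trace(spec))
  true_slope <- -10 * 3e-6 / 3600 * 6220 * 0.5
  expect_lt(abs(fit$slope - true_slope), 3 * fit$slope_se)
  # saturated traces are truncated before A340 <= 0.05
  sat <- data.frame(time_s = t, a340 = pmax(1 - 4e-4 * t, 0.02))
  f <- fit_linear_rate(sat)
  expect_true(f$truncated)
  expect_equal(f$slope, -4e-4, tolerance = 1e-9)
})

test_that("specific activity conversion has the right units and linearity", {
  ctx <- assay_context(enzyme_conc = 3, epsilon_340 = 6220, path_length = 0.5)
  # Delta A340 of 0.0187 over 1 h at 3 uM enzyme ~ 2 GTP/enzyme/hr
  slope <- -0.0187 / 3600
  est <- trace_to_turnover(slope, ctx)
  expect_equal(est$rate, 2.0, tolerance = 0.01)
  expect_equal(trace_to_turnover(0, ctx)$rate, 0)
  # doubling enzyme halves the rate for a fixed slope
  ctx2 <- assay_context(enzyme_conc = 6, epsilon_340 = 6220, path_length = 0.5)
  expect_equal(trace_to_turnover(slope, ctx2)$rate, est$rate / 2)
  # linear in |slope|
  expect_equal(trace_to_turnover(3 * slope, ctx)$rate, 3 * est$rate)
  # background steeper than sample clamps at zero
  clamped <- trace_to_turnover(-1e-6, ctx, background_slope = -2e-6)
  expect_equal(clamped$rate, 0)
  expect_true(clamped$clamped)
})

test_that("full coupled round trip returns the generator turnover", {
  ctx <- assay_context(3, 6220, 0.5)
  for (r in c(0.1, 2, 12, 25, 100)) {
    spec <- coupled_assay_spec(enzyme_conc = 3, true_turnover = r,
                               a340_start = if (r > 50) 2 else 1,
                               noise_sd = 0)
    est <- trace_to_turnover(fit_linear_rate(gen_coupled_trace(spec))$slope, ctx)
    expect_equal(est$rate, r, tolerance = 1e-6)
  }
})

test_that("malachite standard curve and endpoint conversion round trip", {
  plate <- gen_malachite_plate(malachite_plate_spec(sample_true_pi = c(9, 93),
                                                    noise_sd = 0))
  curve <- malachite_standard_fit(plate$standards)
  expect_equal(curve$slope, 0.008, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.05, tolerance = 1e-12)
  ctx <- assay_context(enzyme_conc = 3)
  # [Pi] = 9 uM over 1 h at 3 uM enzyme -> 3 GTP/enzyme/hr
  est <- endpoint_to_turnover(plate$samples$a590[1], curve, ctx)
  expect_equal(est$rate, 3, tolerance = 1e-9)
  # blank-level endpoint -> 0
  expect_equal(endpoint_to_turnover(curve$intercept, curve, ctx)$rate, 0)
  # noisy standards: slope within 3 SE of truth
  noisy <- gen_malachite_plate(malachite_plate_spec(noise_sd = 0.01, seed = 6))
  fit <- stats::lm(a590 ~ pi_uM, data = noisy$standards)
  se <- summary(fit)$coefficients["pi_uM", "Std. Error"]
  expect_lt(abs(malachite_standard_fit(noisy$standards)$slope - 0.008), 3 * se)
  # guards
  expect_error(malachite_standard_fit(plate$standards[1, ]), "at least 3")
  expect_error(malachite_standard_fit(
    data.frame(pi_uM = c(0, 10, 20), a590 = c(0.5, 0.3, 0.1))), "slope")
  expect_true(endpoint_to_turnover(2, curve, ctx)$extrapolated)
})

test_that("fold stimulation is a plain ratio with its scaling laws", {
  expect_equal(fold_stimulation(12, 2), 6)
  expect_equal(fold_stimulation(25, 12), 25 / 12)
  expect_equal(fold_stimulation(5, 5), 1)
  k <- 3.7
  expect_equal(fold_stimulation(k * 8, 2), k * fold_stimulation(8, 2))
  expect_error(fold_stimulation(1, 0), "reference")
})

test_that("titration analysis recovers hyperbolic parameters and saturation", {
  x <- c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12)
  y <- 5 + 100 * x / (0.3 + x)
  fit <- titration_analysis(x, y)
  expect_equal(fit$K, 0.3, tolerance = 0.05 * 0.3)
  expect_equal(fit$Amax, 100, tolerance = 0.05 * 100)
  expect_true(fit$saturated)
  # smallest tested concentration at >= 95% of the fitted plateau
  expect_equal(fit$saturation_conc, 6)
  expect_equal(fit$saturation_conc,
               x[which(fit$fitted >= 0.95 * (fit$A0 + fit$Amax))[1]])
  # a shallow curve (K comparable to the tested range) never saturates
  fit2 <- titration_analysis(x, 5 + 100 * x / (1 + x))
  expect_false(fit2$saturated)
  expect_true(is.na(fit2$saturation_conc))
  # hyperbola midpoint: at x = K activity is half of Amax above baseline
  expect_equal(fit$A0 + fit$Amax * fit$K / (fit$K + fit$K),
               fit$A0 + fit$Amax / 2)
  # monotone-decreasing series violates the model
  expect_error(titration_analysis(c(0, 1, 2, 4), c(100, 80, 60, 40)),
               "does not apply")
})
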