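test_that("noiseless GTT profile has the stated shape", {
  blood <- generate_blood_gtt(noise_cv = 0)
  p <- gtt_params()
  expect_equal(blood$values[which.max(blood$values)], p$peak)
  expect_equal(blood$times[which.max(blood$values)], p$t_peak)
  # value at the stationary time within 2% of the stationary concentration
  v80 <- series_at(blood, p$t_stationary)
  expect_lt(abs(v80 - p$stationary) / p$stationary, 0.02)
  # monotone rise from injection to peak
  rise <- blood$values[blood$times >= p$t_injection & blood$times <= p$t_peak]
  expect_true(all(diff(rise) > 0))
  expect_equal(series_at(blood, 0), p$baseline)
  expect_error(gtt_params(t_peak = 90), "t_injection < t_peak")
  expect_error(gtt_params(peak = 90), "peak must exceed")
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_blood_gtt(seed = 7, noise_cv = 0.05)
  b <- generate_blood_gtt(seed = 7, noise_cv = 0.05)
  expect_identical(a, b)
  c <- generate_blood_gtt(seed = 8, noise_cv = 0.05)
  expect_false(identical(a$values, c$values))
  s1 <- make_scenario("rat", seed = 3)
  s2 <- make_scenario("rat", seed = 3)
  expect_identical(s1, s2)
})

test_that("fluorescent readout is decreasing in glucose and inverts exactly", {
  fp <- fluorescence_params(I0 = 1000, K = 180, cv = 0)
  g <- glucose_series(c(0, 10, 20), c(0, 180, 400))
  intens <- fluorescence_readout(g, fp)
  expect_equal(intens$values[1], 1000)        # no quenching at C = 0
  expect_equal(intens$values[2], 500)         # half-quench at C = K
  expect_true(all(diff(intens$values) < 0))   # strictly decreasing
  back <- calibrate_fluorescence(intens, fp)
  expect_equal(back$values, g$values, tolerance = 1e-12)
})

test_that("fluorescent noise is multiplicative and calibration clamps impossibilities", {
  fp <- fluorescence_params(cv = 0.05)
  g <- glucose_series(seq(0, 90, 10), rep(150, 10))
  noisy <- fluorescence_readout(g, fp, seed = 1)
  expect_true(all(noisy$values > 0))
  clean <- fluorescence_readout(g, fluorescence_params(cv = 0))
  cv_hat <- stats::sd(noisy$values / clean$values)
  expect_lt(abs(cv_hat - 0.05), 0.05) # loose: only 10 draws
  # intensity above I0 implies negative concentration -> clamped with warning
  high <- structure(list(times = 0, values = fp$I0 * 1.1,
                         label = "fluorescence", units = "au"),
                    class = "glucose_series")
  expect_warning(out <- calibrate_fluorescence(high, fp), "clamped")
  expect_equal(out$values, 0)
})

test_that("isotope readout preserves the concentration ratio without noise", {
  tt <- seq(0, 30, 10)
  cb <- glucose_series(tt, c(200, 300, 250, 220))
  ci <- glucose_series(tt, c(100, 150, 125, 220), label = "isf")
  act <- isotope_readout(cb, ci, specific_activity = 10, noise = FALSE)
  expect_equal(act$t_blood$values / act$t_isf$values,
               cb$values / ci$values, tolerance = 1e-12)
  expect_equal(act$t_blood$values[4], act$t_isf$values[4]) # equal conc -> equal counts
  # conversion roundtrip recovers the ISF series exactly
  back <- isotope_to_concentration(act$t_blood$values, act$t_isf$values,
                                   cb$values)
  expect_equal(back, ci$values, tolerance = 1e-12)
})

test_that("isotope conversion matches hand arithmetic", {
  expect_equal(isotope_to_concentration(1000, 1000, 180), 180)
  expect_equal(isotope_to_concentration(2000, 1000, 180), 90)
  expect_equal(isotope_to_concentration(1000, 0, 180), 0)
  expect_error(isotope_to_concentration(0, 10, 180), "t_blood")
})

test_that("Poisson counting noise has CV close to 1/sqrt(lambda)", {
  lam <- 1e4
  cb <- glucose_series(seq_len(1000), rep(lam / 10, 1000))
  act <- isotope_readout(cb, cb, specific_activity = 10, seed = 2, noise = TRUE)
  cv_hat <- stats::sd(act$t_blood$values) / mean(act$t_blood$values)
  expect_equal(cv_hat, 1 / sqrt(lam), tolerance = 0.1)
})

test_that("scenarios bundle coherent series and show a positive ISF delay", {
  m <- make_scenario("mouse", seed = 5)
  expect_equal(m$blood$times, seq(0, 100, 10))
  expect_gt(estimate_lag(m$blood, m$isf_true, method = "shift"), 0)
  r <- make_scenario("rat", seed = 5)
  expect_equal(r$isf_measured$times[1], 5) # first sample 5 min after injection
  t_peak_b <- r$blood$times[which.max(r$blood$values)]
  t_peak_i <- r$isf_measured$times[which.max(r$isf_measured$values)]
  expect_gt(t_peak_i, t_peak_b)
  # species-calibrated diffusion time scale
  expect_equal(r$config$tissue$D, calibrate_D(2.4, 24))
  expect_equal(m$config$tissue$D, calibrate_D(2.0, 24))
})

test_that("calibrate_D inverts the half-rise relation", {
  D <- calibrate_D(2.4, 24)
  tis <- tissue_params(D = D, x = 24, C_isf0 = 0)
  # at t = 2.4 min the step response sits at half its final change
  expect_equal(erf_step_response(1, tis, 2.4), 0.5, tolerance = 1e-9)
})
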