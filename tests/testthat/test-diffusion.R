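test_that("error function matches an independent quadrature oracle", {
  # oracle: direct numerical integration of (2/sqrt(pi)) exp(-u^2)
  erf_oracle <- function(z) {
    2 / sqrt(pi) * stats::integrate(function(u) exp(-u^2), 0, z,
                                    rel.tol = 1e-12)$value
  }
  expect_equal(erf_value(0), 0)
  expect_equal(erf_value(6), 1, tolerance = 1e-9)
  for (z in c(0.25, 1, 1.8)) {
    expect_equal(erf_value(z), erf_oracle(z), tolerance = 1e-10)
    expect_equal(erf_value(-z), -erf_value(z)) # odd
  }
  expect_equal(erf_value(1), 0.8427008, tolerance = 1e-7)
})

test_that("step response honors boundary, initial and far-field conditions", {
  tis <- tissue_params(D = 600, x = 0, C_isf0 = 100)
  expect_equal(erf_step_response(200, tis, 5), 200)
  tis24 <- tissue_params(D = 600, x = 24, C_isf0 = 100)
  expect_equal(erf_step_response(200, tis24, 0), 100) # initial condition
  # x/(2 sqrt(Dt)) = 1  =>  C = 200 - 100 * erf(1)
  t_arg1 <- (24 / 2)^2 / 600
  expect_equal(erf_step_response(200, tis24, t_arg1), 200 - 100 * erf_value(1),
               tolerance = 1e-12)
  # t -> infinity: boundary value; x -> infinity: initial value
  expect_equal(erf_step_response(200, tis24, 1e9), 200, tolerance = 1e-4)
  tis_far <- tissue_params(D = 600, x = 1e6, C_isf0 = 100)
  expect_equal(erf_step_response(200, tis_far, 10), 100, tolerance = 1e-9)
  expect_error(erf_step_response(200, tis24, -1), "t must be")
})

test_that("series response modes coincide for constant boundaries", {
  tis <- tissue_params(D = 600, x = 24, C_isf0 = 100)
  bd_eq <- glucose_series(seq(0, 30, 5), rep(150, 7))
  tis_eq <- tissue_params(D = 600, x = 24, C_isf0 = 150)
  for (mode in c("quasi_static", "superposition")) {
    expect_equal(erf_series_response(bd_eq, tis_eq, mode = mode)$values,
                 rep(150, 7), tolerance = 1e-9)
  }
  bd <- glucose_series(seq(0, 30, 5), rep(200, 7))
  analytic <- erf_step_response(200, tis, bd$times)
  expect_equal(erf_series_response(bd, tis, mode = "quasi_static")$values,
               analytic, tolerance = 1e-9)
  expect_equal(erf_series_response(bd, tis, mode = "superposition")$values,
               analytic, tolerance = 1e-9)
})

test_that("finite-difference oracle reproduces the analytic step response", {
  tis <- tissue_params(D = 600, x = 24, C_isf0 = 100)
  bd <- glucose_series(seq(0, 30, 5), rep(200, 7))
  analytic <- erf_step_response(200, tis, bd$times)
  fd <- fd_oracle(bd, tis)
  expect_lt(max(abs(fd$values - analytic)) / max(analytic), 0.005)
  # equilibrium boundary gives a constant field
  bd_eq <- glucose_series(seq(0, 20, 5), rep(100, 5))
  expect_equal(fd_oracle(bd_eq, tis)$values, rep(100, 5), tolerance = 1e-9)
})

test_that("finite-difference error shrinks at least 2x under grid refinement", {
  tis <- tissue_params(D = 600, x = 24, C_isf0 = 100)
  bd <- glucose_series(seq(0, 30, 5), rep(200, 7))
  analytic <- erf_step_response(200, tis, bd$times)
  e_coarse <- max(abs(fd_oracle(bd, tis, grid = list(dx = 2, dt = 0.2))$values - analytic))
  e_fine <- max(abs(fd_oracle(bd, tis, grid = list(dx = 1, dt = 0.1))$values - analytic))
  expect_gt(e_coarse / e_fine, 2)
})

test_that("superposition agrees with the PDE oracle on piecewise-linear boundaries", {
  set.seed(11)
  for (i in 1:8) {
    bd <- random_boundary()
    tis <- random_tissue()
    sup <- erf_series_response(bd, tis, mode = "superposition")
    fd <- fd_oracle(bd, tis)
    expect_lt(max(abs(sup$values - fd$values)) / max(fd$values), 0.01)
  }
})

test_that("maximum principle holds for both modes on random boundaries", {
  set.seed(23)
  for (i in 1:20) {
    bd <- random_boundary()
    tis <- random_tissue()
    lo <- min(c(bd$values, tis$C_isf0)); hi <- max(c(bd$values, tis$C_isf0))
    for (mode in c("quasi_static", "superposition")) {
      v <- erf_series_response(bd, tis, mode = mode,
                               out_times = seq(0, 40, 0.5))$values
      expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
    }
  }
})

test_that("step-up response is nondecreasing in t and nonincreasing in x", {
  bd <- glucose_series(c(0, 40), c(250, 250))
  tt <- seq(0, 40, 0.5)
  prev <- NULL
  for (x in c(5, 15, 25, 35)) {
    tis <- tissue_params(D = 600, x = x, C_isf0 = 100)
    v <- erf_series_response(bd, tis, mode = "superposition", out_times = tt)$values
    expect_true(all(diff(v) >= -1e-9))
    if (!is.null(prev)) expect_true(all(v <= prev + 1e-9))
    prev <- v
  }
})

test_that("half-rise time after a boundary step scales as x^2/D", {
  half_rise <- function(x, D) {
    tis <- tissue_params(D = D, x = x, C_isf0 = 100)
    tt <- seq(0, 60, 0.001)
    tt[which(erf_step_response(200, tis, tt) >= 150)[1]]
  }
  r_x <- half_rise(24, 300) / half_rise(12, 300) # doubling x -> 4x
  expect_equal(r_x, 4, tolerance = 0.02)
  r_D <- half_rise(24, 300) / half_rise(24, 600) # halving D -> 2x
  expect_equal(r_D, 2, tolerance = 0.02)
})

test_that("input validation", {
  expect_error(tissue_params(D = 0), "D must be")
  expect_error(tissue_params(x = -2), "x must be")
  expect_error(fd_oracle(glucose_series(0:5, rep(100, 6)),
                         tissue_params(x = 0)), "x > 0")
})
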