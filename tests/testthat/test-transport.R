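test_that("extraction matches hand arithmetic and flags reverse transport", {
  expect_equal(extraction(100, 100), 0)
  expect_equal(extraction(100, 0), 1)
  expect_equal(extraction(120, 90), 0.25)
  expect_message(e <- extraction(100, 120), "negative extraction")
  expect_equal(e, -0.2)
  expect_error(extraction(0, 50), "c_arterial")
  expect_error(extraction(-10, 50), "c_arterial")
})

test_that("Fick wall concentration matches the closed form and its limits", {
  # k = 1: C * exp(-1)
  expect_equal(fick_isf_concentration(200, unit_k(1)), 200 * exp(-1),
               tolerance = 1e-12)
  # k -> infinity: full equilibration with blood
  expect_equal(fick_isf_concentration(200, unit_k(1e6)), 200,
               tolerance = 1e-3)
  # k -> 0+: nothing crosses (default zero back-concentration)
  expect_lt(fick_isf_concentration(200, unit_k(1e-9)), 1e-3)
  expect_equal(fick_isf_concentration(0, unit_k(2)), 0)
  expect_error(fick_isf_concentration(-5, unit_k(1)), "c_blood")
})

test_that("Fick wall concentration is monotone in k and bounded", {
  ks <- 10^seq(-6, 6, length.out = 100)
  vals <- vapply(ks, function(k) fick_isf_concentration(180, unit_k(k)),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0 & vals <= 180))
})

test_that("gradient form interpolates between ISF and blood and fixes equilibrium", {
  p <- unit_k(1)
  # reduces to the printed form at zero back-concentration
  expect_equal(fick_isf_concentration(200, p, c_isf = 0),
               fick_isf_concentration(200, p))
  # equilibrium is preserved
  expect_equal(fick_isf_concentration(120, p, c_isf = 120), 120)
  # hand evaluation: 200 - (1 - e^-1) * (200 - 100)
  expect_equal(fick_isf_concentration(200, p, c_isf = 100),
               200 - (1 - exp(-1)) * 100, tolerance = 1e-12)
  # convex combination of the two inputs
  for (k in c(0.1, 1, 5)) {
    v <- fick_isf_concentration(250, unit_k(k), c_isf = 90)
    expect_gte(v, 90); expect_lte(v, 250)
  }
})

test_that("Renkin-Crone consistency: extraction from simulated venous equals 1 - exp(-k)", {
  for (k in c(0.2, 1, 2.5)) {
    p <- unit_k(k)
    cv <- venous_concentration(150, p, c_isf = 0)
    expect_equal(extraction(150, cv), 1 - exp(-k), tolerance = 1e-6)
  }
})

test_that("Starling fluxes match hand-evaluated closed forms", {
  f1 <- starling_fluxes(starling_params(1, 25, 35, 15))
  expect_equal(f1$J_gain, 2.5); expect_equal(f1$J_loss, 2.5)
  expect_equal(f1$w_gain, 0.5)
  # degenerate filtration segment
  f2 <- starling_fluxes(starling_params(1, 35, 35, 15))
  expect_equal(f2$J_gain, 0); expect_equal(f2$J_loss, 10)
  f3 <- starling_fluxes(starling_params(2, 20, 40, 10))
  expect_equal(f3$J_gain, 2 * 400 / 60, tolerance = 1e-12)
  expect_equal(f3$J_loss, 2 * 100 / 60, tolerance = 1e-12)
  expect_error(starling_params(1, 50, 40, 10), "sigma_pi_c")
  expect_error(starling_params(1, 5, 40, 10), "sigma_pi_c")
  expect_error(starling_params(1, 20, 10, 40), "P_a")
})

test_that("closed forms agree with quadrature on random valid draws", {
  set.seed(42)
  for (i in 1:100) {
    sp <- random_starling()
    a <- starling_fluxes(sp, method = "closed_form")
    b <- starling_fluxes(sp, method = "quadrature")
    denom <- max(a$J_gain + a$J_loss, 1e-12)
    expect_lt(abs(a$J_gain - b$J_gain) / denom, 1e-9)
    expect_lt(abs(a$J_loss - b$J_loss) / denom, 1e-9)
  }
})

test_that("Starling mixing is the flux-weighted convex combination", {
  expect_equal(starling_mix(300, 100, new_starling_fluxes(2, 2)), 200)
  expect_equal(starling_mix(300, 100, new_starling_fluxes(5, 0)), 300)
  expect_equal(starling_mix(300, 100, new_starling_fluxes(3, 1)), 250)
  expect_error(new_starling_fluxes(0, 0), "J_gain \\+ J_loss")
  set.seed(7)
  for (i in 1:50) {
    cb <- runif(1, 0, 400); ci <- runif(1, 0, 400)
    fl <- new_starling_fluxes(runif(1, 0, 5), runif(1, 1e-6, 5))
    v <- starling_mix(cb, ci, fl)
    expect_gte(v, min(cb, ci) - 1e-12)
    expect_lte(v, max(cb, ci) + 1e-12)
  }
})

test_that("capillary pressure profile is linear from P_a to P_v", {
  sp <- starling_params(1, 25, 35, 15)
  expect_equal(capillary_pressure(sp, 0), 35)
  expect_equal(capillary_pressure(sp, 1), 15)
  expect_equal(capillary_pressure(sp, 0.5), 25)
  expect_error(capillary_pressure(sp, 1.5), "x_axial")
})

test_that("capillary parameter validation rejects nonpositive values", {
  expect_error(capillary_params(permeability = 0), "permeability")
  expect_error(capillary_params(flow = -1), "flow")
  expect_equal(capillary_params(2, 3, 4)$k, 1.5)
})
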