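# PBTK model: parameter construction, conservation, linearity, closed-form
# agreement, monotonicity, steady-state attainment.

test_that("whole-liver clearance scaling follows the unit conversion", {
  p <- build_parameters(list(fub = 0.5, clint = 10),
                        overrides = list(hepatocellularity = 110,
                                         liver_mass = 1800))
  expect_equal(p$clint_scaled, 10 * 110 * 1800 * 60 / 1e9)  # = 118.8 L/h
  expect_equal(p$clint_scaled, 0.1188)
  p0 <- build_parameters(list(fub = 0.5, clint = 0))
  expect_identical(p0$clint_scaled, 0)
})

test_that("invalid physiology overrides are refused", {
  rec <- list(fub = 0.5, clint = 10)
  expect_error(build_parameters(rec, overrides = list(gfr = -1)), "gfr")
  expect_error(build_parameters(rec, overrides = list(nonsense = 1)),
               "unknown parameter")
  expect_error(build_parameters(list(fub = 1.5, clint = 10)), "fub")
  expect_error(build_parameters(list(fub = 0.5, clint = -2)), "clint")
  # regional flows exceeding cardiac output break circulatory closure
  expect_error(build_parameters(rec, overrides = list(q_kidney = 400)),
               "cardiac output")
})

test_that("analytic Css is linear through the origin with a renal-only limit", {
  p <- build_parameters(list(fub = 0.3, clint = 20))
  expect_identical(css_analytic(p, 0), 0)
  set.seed(1)
  d <- runif(20, 0.01, 50)
  expect_equal(css_analytic(p, 2 * d), 2 * css_analytic(p, d),
               tolerance = 1e-10)
  # clint = 0, fub = 1: clearance is glomerular filtration only
  pr <- build_parameters(list(fub = 1, clint = 0))
  expect_equal(css_analytic(pr, 3),
               3 * pr$body_weight * pr$f_abs / (24 * pr$gfr),
               tolerance = 1e-12)
  # no clearance pathway at all
  pz <- build_parameters(list(fub = 1, clint = 0),
                         overrides = list(gfr = 0))
  expect_error(css_analytic(pz, 1), "no clearance pathway")
})

test_that("Css-dose curves are pointwise analytic and monotone", {
  p <- build_parameters(list(fub = 0.2, clint = 5))
  g <- css_vs_dose(p, c(0, 1, 2))
  expect_equal(g$css[1], 0)
  expect_equal(g$css[3], 2 * g$css[2], tolerance = 1e-12)
  expect_identical(nrow(css_vs_dose(p, 7)), 1L)
  grid <- seq(0, 10, length.out = 100)
  expect_equal(css_vs_dose(p, grid)$css,
               vapply(grid, function(d) css_analytic(p, d), numeric(1)))
  expect_true(all(diff(css_vs_dose(p, grid)$css) >= 0))
})

test_that("zero dose produces identically zero concentrations", {
  p <- build_parameters(list(fub = 0.5, clint = 10))
  sim <- simulate_regimen(p, dosing_regimen(0, 1, 2))
  expect_true(all(sim$c_plasma == 0))
  expect_identical(sim$css, 0)
})

test_that("simulated mass balance closes and matches the closed form", {
  set.seed(42)
  for (i in 1:5) {
    fub <- exp(runif(1, log(0.01), log(1)))
    clint <- runif(1, 0, 100)
    p <- build_parameters(list(fub = fub, clint = clint))
    days <- max(3L, ceiling(7 * log(2) / cholmech:::effective_kel(p) / 24) + 1L)
    sim <- simulate_regimen(p, dosing_regimen(1, 1, days))
    expect_lt(mass_balance_error(sim), 1e-3)
    expect_lt(abs(sim$css - css_analytic(p, 1)) / css_analytic(p, 1), 0.05)
  }
})

test_that("simulated Css is proportional to the daily dose", {
  p <- build_parameters(list(fub = 0.4, clint = 15))
  s1 <- simulate_regimen(p, dosing_regimen(1, 1, 5))
  s3 <- simulate_regimen(p, dosing_regimen(3, 1, 5))
  expect_lt(abs(s3$css - 3 * s1$css) / (3 * s1$css), 1e-4)
})

test_that("Css decreases with clearance drivers, all else fixed", {
  css_at <- function(fub, clint) {
    css_analytic(build_parameters(list(fub = fub, clint = clint)), 1)
  }
  clints <- c(0, 1, 5, 20, 100)
  expect_true(all(diff(vapply(clints, function(cl) css_at(0.5, cl),
                              numeric(1))) < 0))
  fubs <- c(0.05, 0.1, 0.3, 0.6, 1)
  expect_true(all(diff(vapply(fubs, function(f) css_at(f, 10),
                              numeric(1))) < 0))
})

test_that("the profile is periodic once past seven half-lives", {
  p <- build_parameters(list(fub = 0.5, clint = 10))
  days <- max(3L, ceiling(7 * log(2) / cholmech:::effective_kel(p) / 24) + 1L)
  sim <- simulate_regimen(p, dosing_regimen(1, 1, days))
  t_end <- days * 24
  last <- sim$times > t_end - 24
  prev <- sim$times > t_end - 48 & sim$times <= t_end - 24
  peak_diff <- abs(max(sim$c_plasma[last]) - max(sim$c_plasma[prev])) /
    max(sim$c_plasma[prev])
  trough_diff <- abs(min(sim$c_plasma[last]) - min(sim$c_plasma[prev])) /
    max(min(sim$c_plasma[prev]), 1e-12)
  expect_lt(peak_diff, 0.01)
  expect_lt(trough_diff, 0.01)
})

test_that("multiple daily doses flatten the profile without changing the average", {
  p <- build_parameters(list(fub = 0.5, clint = 10))
  s1 <- simulate_regimen(p, dosing_regimen(1, 1, 6))
  s4 <- simulate_regimen(p, dosing_regimen(1, 4, 6))
  expect_equal(s1$css, s4$css, tolerance = 0.02)
  last1 <- s1$times > 5 * 24; last4 <- s4$times > 5 * 24
  fluct <- function(x) diff(range(x)) / mean(x)
  expect_lt(fluct(s4$c_plasma[last4]), fluct(s1$c_plasma[last1]))
})
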