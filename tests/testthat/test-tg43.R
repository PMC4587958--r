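# TG-43 formalism: geometry factor against numerical line integration,
# S_K and Lambda algebra, closed-form g_L / F recovery, forward
# reconstruction round trip.

test_that("geometry factor agrees with numerical line integration", {
  for (r in c(0.25, 0.5, 1, 2, 5, 10, 20))
    for (th in c(1, 5, 30, 60, 90, 120, 150, 179))
      expect_equal(geometry_factor_line(r, th), gl_numeric(r, th),
                   tolerance = 1e-6)
})

test_that("geometry factor limits are exact", {
  # reference value at (1 cm, 90 deg): beta = 2 atan(L/2)
  expect_equal(geometry_factor_line(1, 90),
               2 * atan(0.175) / 0.35, tolerance = 1e-12)
  expect_equal(geometry_factor_line(1, 90), 0.98998, tolerance = 1e-4)
  # far field converges to inverse square (analytic deviation is
  # (L/2r)^2/3 = 1.02e-4 at r = 10 cm)
  expect_equal(geometry_factor_line(10, 90) * 100, 1, tolerance = 2e-4)
  # L -> 0 reduces to a point source
  expect_equal(geometry_factor_line(2, 37, L_cm = 1e-9), 1 / 4,
               tolerance = 1e-6)
  # on-axis analytic limit, equal to the closed-form line integral
  expect_equal(geometry_factor_line(1, 0), 1 / (1 - 0.35^2 / 4))
  expect_equal(geometry_factor_line(2, 180), 1 / (4 - 0.35^2 / 4))
  expect_error(geometry_factor_line(0.1, 0), "active line")
})

test_that("air kerma strength is kerma times squared distance", {
  expect_equal(air_kerma_strength(1, 1), 1)
  expect_equal(air_kerma_strength(4, 0.5), 1)
  expect_error(air_kerma_strength(-1, 1), "positive")
})

test_that("dose rate constant is the reference ratio in TG-43 units", {
  lam <- dose_rate_constant(1.108e-4 * 1e-12, 1e-16,
                            rel_unc_d = 0.003, rel_unc_sk = 0.004)
  expect_equal(lam$lambda, 1.108e-4 * 1e-12 / 1e-16 * 1e-4)
  expect_equal(lam$rel_uncertainty_k1, sqrt(0.003^2 + 0.004^2))
  # linearity in the reference dose
  expect_equal(dose_rate_constant(2, 1)$lambda,
               2 * dose_rate_constant(1, 1)$lambda)
  expect_error(dose_rate_constant(1, 0), "positive")
})

test_that("radial dose function recovers closed-form constructions", {
  r <- c(0.25, 0.5, 1, 2, 5, 10, 20)
  # pure line-source geometry input: g_L is identically 1
  tab <- data.frame(r_cm = r,
                    kerma_Gy_per_history = 3 * geometry_factor_line(r, 90))
  g <- radial_dose_function(tab)
  expect_equal(g$g_L, rep(1, length(r)), tolerance = 1e-12)
  # exponential modulation is recovered exactly
  a <- 0.11
  tab$kerma_Gy_per_history <- tab$kerma_Gy_per_history * exp(-a * (r - 1))
  g <- radial_dose_function(tab)
  expect_equal(g$g_L, exp(-a * (r - 1)), tolerance = 1e-12)
  expect_equal(g$g_L[r == 1], 1)
  expect_error(radial_dose_function(data.frame(
    r_cm = c(2, 3), kerma_Gy_per_history = c(1, 1))), "r0")
})

test_that("g_L uncertainties combine the two dose entries in quadrature", {
  tab <- data.frame(r_cm = c(1, 5),
                    kerma_Gy_per_history = geometry_factor_line(c(1, 5), 90),
                    rel_uncertainty_k1 = c(0.003, 0.004))
  g <- radial_dose_function(tab)
  expect_equal(g$rel_uncertainty_k1, c(0, sqrt(0.003^2 + 0.004^2)))
})

test_that("anisotropy function normalizes at 90 degrees", {
  grid <- expand.grid(r_cm = c(1, 3), theta_deg = c(10, 45, 90, 170))
  grid$kerma_Gy_per_history <-
    5 * geometry_factor_line(grid$r_cm, grid$theta_deg)
  f <- anisotropy_function(grid)
  expect_equal(f$F, rep(1, nrow(f)), tolerance = 1e-12)
  expect_error(anisotropy_function(data.frame(
    r_cm = 1, theta_deg = 45, kerma_Gy_per_history = 1)), "90")
})

test_that("forward reconstruction is exact at tabulated nodes", {
  r <- c(0.5, 1, 2, 5, 10)
  g <- exp(-0.1 * (r - 1))
  dose <- 1.1 * geometry_factor_line(r, 90) /
    geometry_factor_line(1, 90) * g
  ds <- tg43_dataset(s_k = 1, lambda = 1.1,
                     g_L = data.frame(r_cm = r, g_L = g,
                                      rel_uncertainty_k1 = 0))
  rec <- dose_rate_tg43(ds, r, 90)
  expect_equal(rec$dose_rate, dose, tolerance = 1e-12)
  expect_false(any(rec$extrapolated))
  # reference point gives S_K * Lambda exactly; halving S_K halves dose
  expect_equal(dose_rate_tg43(ds, 1, 90)$dose_rate, 1.1)
  ds2 <- ds; ds2$s_k <- 0.5
  expect_equal(dose_rate_tg43(ds2, r, 90)$dose_rate, rec$dose_rate / 2,
               tolerance = 1e-12)
  # beyond the table the result is flagged
  expect_true(dose_rate_tg43(ds, 15, 90)$extrapolated)
})

test_that("dataset validation enforces the normalization identities", {
  g_ok <- data.frame(r_cm = c(1, 2), g_L = c(1, 0.9),
                     rel_uncertainty_k1 = 0)
  expect_s3_class(tg43_dataset(1e-16, 1.1, g_ok), "tg43_dataset")
  g_bad <- data.frame(r_cm = c(1, 2), g_L = c(1.01, 0.9),
                      rel_uncertainty_k1 = 0)
  expect_error(tg43_dataset(1e-16, 1.1, g_bad), "g_L")
  f_bad <- data.frame(r_cm = 1, theta_deg = 90, F = 0.99)
  expect_error(tg43_dataset(1e-16, 1.1, g_ok, f_bad), "theta0")
})

test_that("Lambda is invariant under history-count rescaling", {
  d_ref <- 4.5e-13; s_k <- 4.2e-17
  l1 <- dose_rate_constant(d_ref, s_k)$lambda
  l2 <- dose_rate_constant(d_ref / 7, s_k / 7)$lambda
  expect_equal(l1, l2, tolerance = 1e-12)
})
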