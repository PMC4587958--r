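# Track-length kerma estimator: chord geometry against an independent
# numerical oracle, closed-form point-source checks, estimator
# consistency, type-A uncertainties.

# independent chord oracle: coarse scan plus bisection-refined crossings
chord_oracle <- function(cell, a, b, n = 1e5) {
  d <- b - a
  len <- sqrt(sum(d^2))
  u <- d / len
  inside <- function(t) {
    p <- a + t * u
    rho2 <- p[1]^2 + p[2]^2
    rho2 >= cell$r1^2 && rho2 <= cell$r2^2 && p[3] >= cell$z1 &&
      p[3] <= cell$z2
  }
  ts <- seq(0, len, length.out = n + 1)
  flags <- vapply(ts, inside, TRUE)
  refine <- function(lo, hi) {  # bisection to 1e-12 on an inside change
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (inside(mid) == inside(lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  total <- 0
  entry <- NA
  for (i in seq_len(n)) {
    if (!flags[i] && flags[i + 1]) entry <- refine(ts[i], ts[i + 1])
    if (flags[i] && !flags[i + 1]) {
      start <- if (flags[1] && is.na(entry)) 0 else entry
      total <- total + refine(ts[i], ts[i + 1]) - start
      entry <- NA
    }
  }
  if (flags[n + 1]) {
    start <- if (is.na(entry)) 0 else entry
    total <- total + len - start
  }
  total
}

test_that("segment scoring matches the numerical chord oracle", {
  cell_df <- data.frame(r_cm = 1.5, theta_deg = 90, r1 = 1, r2 = 2,
                        z1 = -0.5, z2 = 0.5)
  cell <- as.list(cell_df)
  vol <- pi * (4 - 1) * 1
  muen <- 0.03
  segs <- list(
    list(a = c(-3, 0.2, 0), b = c(3, 0.2, 0)),       # full diameter crossing
    list(a = c(0, 0, 0), b = c(3, 0.4, 0.2)),        # from inside the hole
    list(a = c(1.2, 0.3, -1), b = c(1.4, -0.2, 1)),  # axial crossing
    list(a = c(-3, 1.7, 0.1), b = c(3, 1.7, 0.3)),   # chord missing the hole
    list(a = c(1.1, 0, 0), b = c(1.9, 0, 0.2)))      # fully inside
  for (sg in segs) {
    got <- score_segment(cell_df, sg$a, sg$b, energy = 1, weight = 1,
                         mu_en_rho = muen)
    want <- muen * chord_oracle(cell, sg$a, sg$b) / vol * MEV_PER_G_TO_GY
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("segments outside every cell leave the grid unchanged", {
  cells <- ring_cells(c(1, 5))
  out <- score_segment(cells, c(10, 10, 3), c(11, 10, 3), 1.25, 1, 0.03)
  expect_identical(out, c(0, 0))
})

test_that("kerma in a large cell equals its mass-weighted sub-partition", {
  big <- data.frame(r_cm = 1.5, theta_deg = 90, r1 = 1, r2 = 2,
                    z1 = -0.4, z2 = 0.4)
  radii <- seq(1, 2, length.out = 5)
  zs <- seq(-0.4, 0.4, length.out = 3)
  sub <- expand.grid(i = 1:4, j = 1:2)
  sub_df <- data.frame(r_cm = 0, theta_deg = 90,
                       r1 = radii[sub$i], r2 = radii[sub$i + 1],
                       z1 = zs[sub$j], z2 = zs[sub$j + 1])
  vols <- pi * (sub_df$r2^2 - sub_df$r1^2) * (sub_df$z2 - sub_df$z1)
  set.seed(41)
  for (i in 1:50) {
    a <- runif(3, -3, 3)
    b <- runif(3, -3, 3)
    kb <- score_segment(big, a, b, 1.25, 1, 0.0296)
    ks <- score_segment(sub_df, a, b, 1.25, 1, 0.0296)
    expect_equal(kb, sum(ks * vols) / sum(vols), tolerance = 1e-12)
  }
})

test_that("type-A uncertainty behaves like a standard error", {
  expect_equal(rel_uncertainty(rep(3.5, 10)), 0)
  expect_true(is.na(rel_uncertainty(c(0, 0, 0))))
  set.seed(42)
  bm <- rnorm(100, mean = 10, sd = 1)
  want <- 1 / sqrt(100) / 10
  expect_lt(abs(rel_uncertainty(bm) - want) / want, 0.3)
  expect_error(rel_uncertainty(1), "2 batches")
})

test_that("point source in vacuum reproduces inverse-square kerma", {
  cfg <- run_config(histories = 5e5, seed = 43, batches = 10,
                    phantom_side_cm = 250, phantom_medium = "air",
                    vacuum_mode = TRUE, point_source = TRUE,
                    line_weights = c(1, 0))
  tal <- run_simulation(cfg, ring_cells(100, dr_cm = 2, dz_cm = 1),
                        tables = xs_tabs)
  muen <- lookup_mu_en(xs_tabs$air, 1.17)
  want <- 1.17 * muen / (4 * pi * 100^2) * MEV_PER_G_TO_GY
  tol <- 3 * tal$rel_uncertainty_k1 * want
  expect_lt(abs(tal$kerma_Gy_per_history - want), tol)
})

test_that("primary-only kerma follows the exponential closed form", {
  cfg <- run_config(histories = 2e6, seed = 44, batches = 20,
                    primary_only = TRUE, point_source = TRUE,
                    line_weights = c(1, 0))
  d <- c(1, 5, 10)
  tal <- run_simulation(cfg, ring_cells(d, dr_cm = 0.05, dz_cm = 0.05),
                        tables = xs_tabs)
  mu <- lookup_mu(xs_tabs$water, 1.17) * 0.998
  muen <- lookup_mu_en(xs_tabs$water, 1.17)
  want <- 1.17 * muen * exp(-mu * d) / (4 * pi * d^2) * MEV_PER_G_TO_GY
  tol <- 3 * tal$rel_uncertainty_k1 * want
  expect_true(all(abs(tal$kerma_Gy_per_history - want) < tol))
})

test_that("full-physics kerma shows scatter buildup of at least one", {
  d <- c(1, 3, 5)
  cells <- ring_cells(d, dr_cm = 0.05, dz_cm = 0.05)
  cfgP <- run_config(histories = 5e5, seed = 45, batches = 10,
                     primary_only = TRUE, point_source = TRUE)
  cfgF <- run_config(histories = 5e5, seed = 46, batches = 10,
                     point_source = TRUE)
  kp <- run_simulation(cfgP, cells, tables = xs_tabs)
  kf <- run_simulation(cfgF, cells, tables = xs_tabs)
  comb <- sqrt((kp$kerma_Gy_per_history * kp$rel_uncertainty_k1)^2 +
               (kf$kerma_Gy_per_history * kf$rel_uncertainty_k1)^2)
  expect_true(all(kf$kerma_Gy_per_history >
                  kp$kerma_Gy_per_history - 2 * comb))
})

test_that("air kerma in vacuum mode is pure inverse square", {
  cfg <- run_config(histories = 5e5, seed = 47, batches = 10,
                    vacuum_mode = TRUE)
  a <- air_kerma_run(cfg, distances_cm = c(50, 100, 150),
                     tables = xs_tabs, phantom_side_cm = 400)
  kd2 <- a$kerma_Gy_per_history * c(50, 100, 150)^2
  comb <- kd2 * a$rel_uncertainty_k1
  for (i in 2:3)
    expect_lt(abs(kd2[i] - kd2[1]),
              4 * sqrt(comb[i]^2 + comb[1]^2) + 1e-3 * kd2[1])
})

test_that("air scatter and attenuation nearly cancel at one metre", {
  cfgA <- run_config(histories = 1e6, seed = 48, batches = 10)
  cfgV <- run_config(histories = 1e6, seed = 48, batches = 10,
                     vacuum_mode = TRUE)
  ka <- air_kerma_run(cfgA, tables = xs_tabs)
  kv <- air_kerma_run(cfgV, tables = xs_tabs)
  expect_lt(abs(ka$kerma_Gy_per_history / kv$kerma_Gy_per_history - 1),
            0.02)
})

test_that("transverse water kerma decreases over the sixteen distances", {
  cfg <- run_config(histories = 5e5, seed = 49, batches = 10)
  w <- water_dose_run(cfg, tables = xs_tabs)
  expect_equal(nrow(w$dose_table), 16)
  expect_true(all(w$dose_table$kerma_Gy_per_history > 0))
  expect_true(all(diff(w$dose_table$kerma_Gy_per_history) < 0))
})

test_that("mirrored cells across the transverse plane agree", {
  cells <- rbind(ring_cells(3, dr_cm = 0.2, dz_cm = 0.2, z_cm = 2),
                 ring_cells(3, dr_cm = 0.2, dz_cm = 0.2, z_cm = -2))
  cfg <- run_config(histories = 5e5, seed = 50, batches = 10)
  tal <- run_simulation(cfg, cells, tables = xs_tabs)
  k <- tal$kerma_Gy_per_history
  comb <- sqrt(sum((k * tal$rel_uncertainty_k1)^2))
  expect_lt(abs(k[1] - k[2]), 4 * comb)
})
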