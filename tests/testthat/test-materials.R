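# Attenuation tables: validation invariants, log-log interpolation,
# interaction-kind sampling, fixture round trip.

test_that("bundled tables satisfy the structural invariants", {
  for (tab in xs_tabs) {
    E <- tab$energy_MeV
    expect_true(all(diff(E) > 0))
    expect_lte(E[1], 0.010)
    expect_gte(E[length(E)], 1.35)
    expect_equal(tab$f_photo + tab$f_incoh + tab$f_coh + tab$f_pair,
                 rep(1, length(E)), tolerance = 1e-6)
    expect_true(all(tab$f_pair[E < 1.022] == 0))
    expect_true(all(tab$mu_en_rho <= tab$mu_rho + 1e-12))
    expect_true(all(tab$mu_rho > 0) && all(tab$mu_en_rho > 0))
  }
})

test_that("interpolation is exact at grid nodes and log-log in between", {
  for (tab in xs_tabs[c("water", "steel")]) {
    E <- tab$energy_MeV
    expect_equal(lookup_mu(tab, E), tab$mu_rho, tolerance = 1e-12)
    expect_equal(lookup_mu_en(tab, E), tab$mu_en_rho, tolerance = 1e-12)
    # closed form: at the geometric mean of two nodes, log-log linear
    # interpolation returns the geometric mean of the node values
    mid <- sqrt(E[-length(E)] * E[-1])
    expect_equal(lookup_mu(tab, mid),
                 sqrt(tab$mu_rho[-length(E)] * tab$mu_rho[-1]),
                 tolerance = 1e-10)
  }
})

test_that("water attenuation at 1.25 MeV matches the compilation value", {
  expect_equal(lookup_mu(xs_tabs$water, 1.25), 0.0632, tolerance = 1e-3)
})

test_that("interpolated coefficients are positive and continuous", {
  Eg <- exp(seq(log(0.010), log(1.35), length.out = 2000))
  for (tab in xs_tabs) {
    mu <- lookup_mu(tab, Eg)
    men <- lookup_mu_en(tab, Eg)
    expect_true(all(is.finite(mu)) && all(mu > 0))
    expect_true(all(is.finite(men)) && all(men > 0))
    # no discontinuities on a fine grid
    expect_lt(max(abs(diff(log(mu)))), 0.05)
  }
})

test_that("mu_en/rho is monotone decreasing between the gamma lines", {
  Eg <- seq(1.1, 1.35, by = 0.01)
  men <- lookup_mu_en(xs_tabs$water, Eg)
  expect_true(all(diff(men) < 0))
  expect_gt(lookup_mu_en(xs_tabs$water, 1.17),
            lookup_mu_en(xs_tabs$water, 1.33))
})

test_that("steel absorbs more than water below 100 keV", {
  Eg <- xs_tabs$water$energy_MeV
  Eg <- Eg[Eg <= 0.1]
  expect_true(all(lookup_mu_en(xs_tabs$steel, Eg) >=
                  lookup_mu_en(xs_tabs$water, Eg)))
})

test_that("energy outside the table range raises a range error", {
  expect_error(lookup_mu(xs_tabs$water, 0.005), "water")
  expect_error(lookup_mu_en(xs_tabs$air, 2.0), "outside table range")
})

test_that("interaction sampling follows the cumulative branch ordering", {
  # below the pair threshold the pair kind is never drawn
  kinds <- sample_interaction(xs_tabs$water, 0.5, runif(2000))
  expect_false("pair" %in% kinds)
  # u = 0 selects the first kind of the documented ordering
  expect_identical(sample_interaction(xs_tabs$water, 1.25, 0),
                   "photoelectric")
})

test_that("sampled interaction frequencies match the branch fractions", {
  set.seed(4)
  cases <- list(list(tab = xs_tabs$water, E = 1.25),
                list(tab = xs_tabs$water, E = 0.06),
                list(tab = xs_tabs$steel, E = 0.08),
                list(tab = xs_tabs$air, E = 0.3))
  n <- 1e5
  for (cs in cases) {
    f <- branch_fractions(cs$tab, cs$E)
    kinds <- sample_interaction(cs$tab, cs$E, runif(n))
    for (kind in names(f)) {
      if (f[[kind]] == 0) next
      se <- sqrt(f[[kind]] * (1 - f[[kind]]) / n)
      expect_lt(abs(mean(kinds == kind) - f[[kind]]), 4 * se + 1e-12)
    }
  }
})

test_that("writing and re-reading a table is bit-exact", {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_xs_table(xs_tabs$cobalt, tmp)
  back <- read_xs_table(tmp, hdr_materials()$cobalt)
  for (col in c("energy_MeV", "mu_rho", "f_photo", "f_incoh", "f_coh",
                "f_pair", "mu_en_rho"))
    expect_identical(back[[col]], xs_tabs$cobalt[[col]])
})

test_that("material and table validation rejects bad input", {
  expect_error(material("x", 1, c(H = 0.5, O = 0.6)), "sum")
  expect_error(material("x", -1, c(H = 1)), "positive")
  bad <- as.data.frame(unclass(xs_tabs$water)[
    c("energy_MeV", "mu_rho", "f_photo", "f_incoh", "f_coh", "f_pair",
      "mu_en_rho")])
  bad$mu_en_rho[3] <- bad$mu_rho[3] * 1.1
  expect_error(attenuation_table(hdr_materials()$water, bad), "mu_en")
})

test_that("default water density is 0.998 g/cm^3", {
  expect_equal(hdr_materials()$water$density, 0.998)
  expect_equal(xs_tabs$water$density, 0.998)
})
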