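kB <- phys_constants()$kB

test_that("persistence length from buckling matches the independent quadratic-root oracle", {
  # golden value pinned with polyroot on the quadratic coefficients
  lp <- persistence_from_buckling(1.021, 5.95e-9, medium(0.1, Z = 1, T = 298))
  expect_equal(lp, 68.1042001335e-9, tolerance = 1e-10)
  # and lies inside the experimental band at 0.1 M
  expect_gt(lp * 1e9, 40); expect_lt(lp * 1e9, 80)
})

test_that("solved pairs satisfy the polynomial constraint", {
  for (mu in c(0.5, 0.718, 1.021)) {
    for (lcb in c(4e-9, 8e-9, 16e-9)) {
      med <- medium(c(0.01, 0.1, 1))
      lp <- persistence_from_buckling(mu, lcb, med)
      expect_true(all(abs(buckling_residual(lp, mu, lcb, med)) < 1e-8))
    }
  }
})

test_that("null-isomer degenerate limit holds when the electrostatic force vanishes", {
  geom <- dna_geometry()
  for (lcb in c(4e-9, 6e-9, 12e-9)) {
    lp_null <- dnabuckle:::.lp_from_lcb(0.5, lcb, 0, geom)
    expect_equal(lp_null, lcb^3 / (4 * pi^4 * geom$R^2), tolerance = 1e-12)
    # general-mu form of the same limit
    lp_mu <- dnabuckle:::.lp_from_lcb(0.83, lcb, 0, geom)
    expect_equal(lp_mu, 4 * 0.83^4 * lcb^3 / (pi^4 * geom$R^2), tolerance = 1e-12)
  }
})

test_that("electrostatic-only degenerate limit equals the strongly environment-coupled term", {
  med <- medium(c(0.01, 0.1, 1))
  f <- electrostatic_force(med) / (kB * med$T)
  dec <- decompose_persistence(0.718, 8.43e-9, med)
  expect_equal(dec$tsde_nm, 0.718^2 * (8.43e-9)^2 * f / pi^2 * 1e9,
               tolerance = 1e-12)
})

test_that("buckling length inversion round-trips through the forward map", {
  for (mu in c(0.5, 0.8, 1.021, 1.25)) {
    for (lcb in c(4e-9, 8e-9, 16e-9)) {
      med <- medium(c(0.01, 0.1, 1))
      lp <- persistence_from_buckling(mu, lcb, med)
      lcb_back <- buckling_from_persistence(lp, mu, med)
      expect_equal(lcb_back, rep(lcb, 3), tolerance = 1e-6)
    }
  }
})

test_that("buckling length inversion matches the quartic-root oracle on the cyclization case", {
  lcb <- buckling_from_persistence(geggier_lp(298), 0.5, medium(0.1, Z = 1, T = 298))
  expect_equal(lcb, 10.967736016745e-9, tolerance = 1e-9)
})

test_that("zero-force inversion reduces to the cube-root of the null-isomer law", {
  geom <- dna_geometry()
  lp <- 50e-9
  lcb <- dnabuckle:::.lcb_from_lp(lp, 0.5, 0, geom)
  expect_equal(lcb, (4 * pi^4 * geom$R^2 * lp)^(1 / 3), tolerance = 1e-12)
  expect_equal(lcb^3 / (4 * pi^4 * geom$R^2), lp, tolerance = 1e-10)
})

test_that("decomposition terms are non-negative and sum to the full prediction", {
  med <- medium(default_conc_grid(25))
  for (mu in c(0.718, 1.021)) {
    dec <- decompose_persistence(mu, 6e-9, med)
    lp <- persistence_from_buckling(mu, 6e-9, med) * 1e9
    expect_equal(dec$todc_nm + dec$twde_nm + dec$tsde_nm, lp, tolerance = 1e-9)
    expect_equal(dec$lp_nm, lp, tolerance = 1e-12)
    expect_true(all(dec$todc_nm > 0 & dec$twde_nm > 0 & dec$tsde_nm > 0))
  }
})

test_that("constraint-only term ignores salt while the strong term falls with it", {
  dec <- decompose_persistence(1.021, 5.95e-9, medium(exp(seq(log(0.01), log(4), length.out = 60))))
  expect_equal(diff(range(dec$todc_nm)), 0)
  expect_true(all(diff(dec$tsde_nm) < 0))
})

test_that("prediction bands reflect the spread of the effective length factor", {
  flat <- predict_lp_curve(1.021, 5.95e-9, conc = c(0.01, 0.1, 1), sigma_mu = 0)
  expect_equal(flat$lp_lo_nm, flat$lp_nm)
  expect_equal(flat$lp_hi_nm, flat$lp_nm)
  band <- predict_lp_curve(1.021, 5.95e-9, conc = c(0.01, 0.1, 1), sigma_mu = 0.25)
  expect_true(all(band$lp_lo_nm <= band$lp_nm & band$lp_nm <= band$lp_hi_nm))
  # lp is monotone increasing in mu at fixed lcb, so the band is ordered
  lo <- persistence_from_buckling(1.021 - 0.25, 5.95e-9, medium(0.1))
  hi <- persistence_from_buckling(1.021 + 0.25, 5.95e-9, medium(0.1))
  expect_lt(lo, hi)
  expect_error(predict_lp_curve(0.5, 6e-9, sigma_mu = 0.6), "positive")
})
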