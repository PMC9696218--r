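test_that("the cyclization temperature law gives physiological values and decreases with T", {
  expect_equal(geggier_lp(298), 47.5702752651e-9, tolerance = 1e-10)
  Tg <- 278:313
  lp <- geggier_lp(Tg)
  expect_true(all(diff(lp) < 0))
  expect_gt(geggier_lp(293), geggier_lp(298))
})

test_that("gradient transfer reproduces the published intercepts at printed precision", {
  sus <- transfer_gradient(5.95e-9, -0.0359e-9)
  expect_equal(round(sus$intercept_a * 1e9, 2), 16.65)
  fb <- transfer_gradient(8.43e-9, -0.0359e-9)
  expect_equal(round(fb$intercept_a * 1e9, 2), 19.13)
  # passes exactly through the anchor at 298 K
  expect_equal(lcb_at(sus, 298), 5.95e-9, tolerance = 1e-12)
  expect_equal(lcb_at(fb, 298), 8.43e-9, tolerance = 1e-12)
  # zero gradient: intercept equals the anchor value
  expect_equal(transfer_gradient(5.95e-9, 0)$intercept_a, 5.95e-9)
  expect_error(transfer_gradient(-1e-9, 0), "positive")
})

test_that("the linear buckling-length fit recovers an exactly linear input law", {
  a <- 20e-9; g <- -0.03e-9
  # forward-generate lp(T) from the linear lcb law, then recover it
  lp_of_T <- function(T) {
    persistence_from_buckling(0.5, a + g * T, medium(0.1, T = T))
  }
  mdl <- fit_lcb_vs_T(lp_of_T, mu = 0.5, conc = 0.1, T_grid = seq(278, 313, 5))
  expect_equal(mdl$intercept_a, a, tolerance = 1e-9)
  expect_equal(mdl$gradient_g, g, tolerance = 1e-9)
  # two points determine the line exactly
  mdl2 <- fit_lcb_vs_T(lp_of_T, mu = 0.5, conc = 0.1, T_grid = c(280, 300))
  expect_equal(mdl2$intercept_a, a, tolerance = 1e-9)
  expect_equal(mdl2$gradient_g, g, tolerance = 1e-9)
})

test_that("inverting the cyclization law yields a negative buckling-length gradient", {
  mdl <- fit_lcb_vs_T(geggier_lp, mu = 0.5, conc = 0.1, T_grid = seq(278, 313, 5))
  expect_lt(mdl$gradient_g, 0)
  # same order of magnitude as the transferred reference slope (-0.0359 nm/K)
  expect_gt(abs(mdl$gradient_g * 1e9), 0.005)
  expect_lt(abs(mdl$gradient_g * 1e9), 0.2)
})

test_that("predicted persistence length decreases with temperature, faster when suspended", {
  Tg <- seq(278, 313, 1)
  sus <- lp_vs_temperature(transfer_gradient(5.95e-9, -0.0359e-9),
                           mu = 1.021, conc = 0.1, T_grid = Tg)
  fb <- lp_vs_temperature(transfer_gradient(8.43e-9, -0.0359e-9),
                          mu = 0.718, conc = 0.1, T_grid = Tg)
  expect_true(all(diff(sus$lp_nm) < 0))
  expect_true(all(diff(fb$lp_nm) < 0))
  drop_sus <- sus$lp_nm[1] - sus$lp_nm[nrow(sus)]
  drop_fb <- fb$lp_nm[1] - fb$lp_nm[nrow(fb)]
  expect_gt(drop_sus, drop_fb)
})

test_that("with a constant buckling length the residual T-dependence comes from the medium", {
  Tg <- seq(278, 313, 5)
  flat <- lp_vs_temperature(lcb_linear_model(5.95e-9, 0), mu = 1.021,
                            conc = 0.1, T_grid = Tg)
  expect_equal(diff(range(flat$lcb_nm)), 0)
  # lp still varies because F_ele / kB T and eps_r are temperature-dependent
  expect_gt(diff(range(flat$lp_nm)), 0)
})
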