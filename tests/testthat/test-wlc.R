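test_that("mean-square end-to-end distance handles hand-built conformations", {
  L <- 10e-9
  expect_equal(mean_square_end_to_end(make_ensemble(straight_chain(L))), L^2)
  # closed loop: last point returns to the first
  theta <- seq(0, 2 * pi, length.out = 21)
  loop <- cbind(cos(theta), sin(theta), 0) * 1e-9
  expect_equal(mean_square_end_to_end(make_ensemble(loop)), 0)
  # two chains with end-to-end distances 3 and 4 -> mean square 12.5
  e3 <- straight_chain(3); e4 <- straight_chain(4)
  expect_equal(mean_square_end_to_end(make_ensemble(e3, e4)), 12.5)
  # burn-in drops leading conformations
  expect_equal(mean_square_end_to_end(make_ensemble(e3, e4), burn_in = 1), 16)
})

test_that("the end-to-end relation is monotone in lp and inverts to 1e-8", {
  L <- 17e-9
  lps <- seq(5e-9, 500e-9, length.out = 200)
  expect_true(all(diff(wlc_msee(lps, L)) > 0))
  expect_equal(lp_from_msee(wlc_msee(50e-9, L), L), 50e-9, tolerance = 1e-8)
  expect_equal(lp_from_msee(wlc_msee(5e-9, L), L), 5e-9, tolerance = 1e-8)
})

test_that("inversion limits behave: Gaussian coil, near-rod, and unreachable inputs", {
  lp <- 50e-9; L <- 1000 * lp
  # flexible-coil asymptote <h^2> ~ 2 lp L
  expect_equal(lp_from_msee(2 * lp * L, L), lp, tolerance = 0.01)
  # near-rod: msee = 0.9999 L^2 gives a finite lp >> L (series: lp ~ L / (3 (1 - m)))
  L2 <- 17e-9
  lp_rod <- lp_from_msee(0.9999 * L2^2, L2)
  expect_true(is.finite(lp_rod))
  expect_equal(lp_rod, L2 / (3 * 1e-4), tolerance = 0.01)
  # exactly rigid input diverges; beyond-rod input is an error
  expect_identical(lp_from_msee(L2^2, L2), Inf)
  expect_error(lp_from_msee(1.01 * L2^2, L2), "exceeds")
})

test_that("the sampler is seed-deterministic and respects the rigid limit", {
  e1 <- sample_wlc(50e-9, 17e-9, n_segments = 20, n_chains = 5, seed = 9)
  e2 <- sample_wlc(50e-9, 17e-9, n_segments = 20, n_chains = 5, seed = 9)
  expect_identical(e1$conformations, e2$conformations)
  e3 <- sample_wlc(50e-9, 17e-9, n_segments = 20, n_chains = 5, seed = 10)
  expect_false(identical(e1$conformations, e3$conformations))
  # contour length is exact by construction
  expect_equal(contour_lengths(e1), rep(17e-9, 5), tolerance = 1e-9)
  # lp >> L: chains are nearly straight
  rigid <- sample_wlc(1, 17e-9, n_segments = 50, n_chains = 20, seed = 1)
  expect_gt(mean_square_end_to_end(rigid) / (17e-9)^2, 0.999)
})

test_that("sampled tangent correlations decay at the imposed persistence length", {
  lp <- 50e-9; L <- 17e-9; nseg <- 50
  ens <- sample_wlc(lp, L, n_segments = nseg, n_chains = 800, seed = 4)
  ds <- L / nseg
  # average tangent autocorrelation over lags 1..10
  corr <- sapply(1:10, function(k) {
    mean(vapply(ens$conformations, function(m) {
      t <- diff(m); t <- t / sqrt(rowSums(t^2))
      mean(rowSums(t[1:(nseg - k), , drop = FALSE] * t[(1 + k):nseg, , drop = FALSE]))
    }, numeric(1)))
  })
  # log-linear decay with slope -ds/lp
  slope <- coef(lm(log(corr) ~ seq_along(corr)))[2]
  expect_equal(unname(slope), -ds / lp, tolerance = 0.05)
})

test_that("the full estimator pipeline recovers the input persistence length", {
  ens <- sample_wlc(50e-9, 17e-9, n_segments = 100, n_chains = 2000, seed = 21)
  est <- estimate_lp(ens)
  expect_equal(est$lp_nm, 50, tolerance = 0.10)
  # per-frame averaging is an alternative estimator on the same ensemble
  pf <- estimate_lp(ens, method = "per_frame")
  expect_true(is.finite(pf$lp_nm) && pf$lp_nm > 0)
})

test_that("XYZ ensemble files round-trip", {
  ens <- sample_wlc(50e-9, 17e-9, n_segments = 15, n_chains = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_ensemble(ens, path)
  back <- read_xyz_ensemble(path)
  expect_equal(length(back$conformations), 3)
  for (i in 1:3)
    expect_equal(back$conformations[[i]], ens$conformations[[i]],
                 tolerance = 1e-8, ignore_attr = TRUE)
  # malformed files are rejected with a location
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "0 0 0", "1 oops 0", "2 0 0"), bad)
  expect_error(read_xyz_ensemble(bad), "malformed")
})
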