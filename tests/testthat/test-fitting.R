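test_that("goodness of fit matches hand arithmetic and handles degeneracies", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3))$r2, 1)
  expect_equal(goodness_of_fit(c(1, 2, 3), rep(2, 3))$r2, 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4))$r2, 0.5)
  # constant observations: TSS = 0 reported as NA, not a division error
  g <- goodness_of_fit(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(g$r2))
  expect_equal(g$tss, 0)
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})

test_that("dataset constructor validates its records", {
  ok <- tibble::tibble(concentration_M = c(0.01, 0.1, 1), lp_nm = c(60, 50, 45))
  ds <- lp_dataset(ok, T = 298, Z = 1, constraint_class = "suspended")
  expect_s3_class(ds, "lp_dataset")
  expect_error(lp_dataset(ok[1:2, ]), "at least 3")
  bad <- ok; bad$concentration_M[2] <- -1
  expect_error(lp_dataset(bad), "positive")
  dup <- ok; dup$concentration_M[2] <- 0.01
  expect_error(lp_dataset(dup), "unique")
  # metre-valued input column is converted
  m <- tibble::tibble(concentration_M = c(0.01, 0.1, 1), lp_m = c(6e-8, 5e-8, 4.5e-8))
  expect_equal(lp_dataset(m)$lp_nm, c(60, 50, 45))
})

test_that("fitting noiseless model-generated data recovers the true parameters", {
  ds <- generate_lp_dataset(0.8, 7e-9, noise_cv = 0, seed = 1)
  fit <- fit_dataset(ds, seed = 3)
  expect_equal(fit$mu_hat, 0.8, tolerance = 1e-4)
  expect_equal(fit$lcb_hat, 7e-9, tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("fits are seed-deterministic", {
  ds <- generate_lp_dataset(1.0, 6e-9, noise_cv = 0.05, seed = 11)
  f1 <- fit_dataset(ds, seed = 5)
  f2 <- fit_dataset(ds, seed = 5)
  expect_identical(f1$mu_hat, f2$mu_hat)
  expect_identical(f1$lcb_hat, f2$lcb_hat)
  expect_identical(f1$residuals, f2$residuals)
})

test_that("constant-persistence-length data yields the undefined-r2 sentinel", {
  ds <- lp_dataset(tibble::tibble(concentration_M = c(0.01, 0.1, 1),
                                  lp_nm = rep(50, 3)))
  fit <- fit_dataset(ds, n_starts = 4L)
  expect_true(is.na(fit$r2))
  expect_equal(fit$tss, 0)
})

test_that("broom-style accessors expose the fit in tidy form", {
  ds <- generate_lp_dataset(0.8, 7e-9, noise_cv = 0, seed = 1)
  fit <- fit_dataset(ds)
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "lcb_nm"))
  expect_equal(td$estimate, c(fit$mu_hat, fit$lcb_hat * 1e9))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(ds))
  expect_equal(gl$r.squared, fit$r2)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$lp_nm)
})

test_that("class aggregation reproduces the published class means and sample SDs", {
  tab <- experiment_table()
  sus <- aggregate_class(tab[tab$constraint_class == "suspended", ])
  expect_equal(round(sus$mu_mean, 3), 1.021)
  expect_equal(round(sus$mu_sd, 3), 0.250)
  expect_equal(round(sus$lcb_mean_nm, 2), 5.95)
  expect_equal(round(sus$lcb_sd_nm, 2), 2.20)
  fb <- aggregate_class(tab[tab$constraint_class == "fix_bead", ])
  expect_equal(round(fb$mu_mean, 3), 0.718)
  expect_equal(round(fb$mu_sd, 3), 0.075)
  expect_equal(round(fb$lcb_mean_nm, 2), 8.43)
  expect_equal(round(fb$lcb_sd_nm, 2), 1.25)
})

test_that("aggregation requires two fits and returns zero SD for identical inputs", {
  same <- tibble::tibble(mu = c(0.8, 0.8), lcb_nm = c(7, 7))
  agg <- aggregate_class(same)
  expect_equal(agg$mu_sd, 0)
  expect_equal(agg$lcb_sd_nm, 0)
  expect_error(aggregate_class(same[1, ]), "at least 2")
})
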