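fit <- gaussian_two_pool_fit(seed = 23)
prof_r1 <- profile_parameter(fit, "r1", 0.7, 1.5, n = 15)
prof_r2 <- profile_parameter(fit, "r2", 0.2, 0.9, n = 15)
grid <- prediction_grid(fit$data, fit$model, 60)

test_that("solution bands envelope the CI-mesh trajectories and the MLE", {
  band <- solution_set(prof_r1, grid, 0.05)
  y_mle <- solve_model(fit$model, fit$theta_hat[c("r1", "r2")], grid)
  expect_true(all(band$band$lower <= y_mle + 1e-9))
  expect_true(all(band$band$upper >= y_mle - 1e-9))
  # brute force: envelope over all mesh trajectories above the threshold
  lc <- loglik_threshold(0.05, 1)$value
  keep <- which(prof_r1$values >= lc)
  trajs <- sapply(keep, function(i)
    solve_model(fit$model,
                c(r1 = prof_r1$mesh[i],
                  r2 = unname(prof_r1$nuisance[i, "r2"])),
                grid))
  expect_equal(band$band$lower, pmin(apply(trajs, 1, min), y_mle),
               tolerance = 1e-9)
  expect_equal(band$band$upper, pmax(apply(trajs, 1, max), y_mle),
               tolerance = 1e-9)
})

test_that("profiling a pure noise parameter yields a zero-width solution band", {
  m <- two_pool_model(100, 25)
  set.seed(31)
  d <- two_pool_design()
  y <- solve_model(m, c(r1 = 1, r2 = 0.5), d)
  dat <- cbind(d, value = y + rnorm(length(y), 0, 5))
  f <- find_mle(dat, m, error_model("gaussian_additive"),
                lower = c(r1 = 0.01, r2 = 0.01, sigma_N = 0.5),
                upper = c(r1 = 5, r2 = 5, sigma_N = 50),
                start = c(r1 = 1, r2 = 0.5, sigma_N = 5))
  ps <- profile_parameter(f, "sigma_N", 2.5, 9, n = 10)
  band <- solution_set(ps, grid, 0.05)
  expect_equal(band$band$lower, band$band$upper, tolerance = 1e-9)
})

test_that("unions are identities on singletons and pointwise supersets", {
  b1 <- solution_set(prof_r1, grid, 0.05)
  b2 <- solution_set(prof_r2, grid, 0.05)
  u <- union_bands(list(b1, b2))
  expect_equal(union_bands(list(b1))$band, b1$band)
  for (b in list(b1, b2)) {
    expect_true(all(u$band$lower <= b$band$lower + 1e-12))
    expect_true(all(u$band$upper >= b$band$upper - 1e-12))
  }
  grid2 <- prediction_grid(fit$data, fit$model, 30)
  b3 <- solution_set(prof_r1, grid2, 0.05)
  expect_error(union_bands(list(b1, b3)), "identical prediction grid")
})

test_that("MLE realization band is the Gaussian quantile band about the MLE", {
  band <- mle_realization_set(fit, grid, 0.05)
  y_mle <- solve_model(fit$model, fit$theta_hat[c("r1", "r2")], grid)
  expect_equal(band$band$lower, y_mle - qnorm(0.975) * 5, tolerance = 1e-9)
  expect_equal(band$band$upper, y_mle + qnorm(0.975) * 5, tolerance = 1e-9)
  # stricter level contains the looser one
  wide <- mle_realization_set(fit, grid, 0.01)
  expect_true(all(wide$band$lower <= band$band$lower))
  expect_true(all(wide$band$upper >= band$band$upper))
})

test_that("Poisson realization band collapses to [0, 0] where the mean is zero", {
  m <- exp_decay_model(0)   # trajectory identically zero
  d <- obs_design(c(1, 2))
  dat <- cbind(d, value = c(0, 0))
  f <- find_mle(dat, m, error_model("poisson"),
                lower = c(r1 = 0.1), upper = c(r1 = 5), start = c(r1 = 1))
  band <- mle_realization_set(f, d, 0.05)
  expect_equal(band$band$lower, c(0, 0))
  expect_equal(band$band$upper, c(0, 0))
})

test_that("Bonferroni band is the enumeration envelope and a superset", {
  band <- bonferroni_realization_set(prof_r1, grid, 0.05)
  # direct enumeration: mesh points above the alpha/2 threshold, each
  # expanded by the alpha/4 Gaussian quantiles (sigma fixed at 5)
  lc <- loglik_threshold(0.025, 1)$value
  keep <- which(prof_r1$values >= lc)
  z <- qnorm(1 - 0.05 / 4)
  trajs <- sapply(c(keep, NA), function(i) {
    th <- if (is.na(i)) fit$theta_hat[c("r1", "r2")]
          else c(r1 = prof_r1$mesh[i],
                 r2 = unname(prof_r1$nuisance[i, "r2"]))
    solve_model(fit$model, th, grid)
  })
  expect_equal(band$band$lower, apply(trajs - z * 5, 1, min),
               tolerance = 1e-9)
  expect_equal(band$band$upper, apply(trajs + z * 5, 1, max),
               tolerance = 1e-9)
  # contains the level 1 - alpha/2 solution set pointwise
  sol <- solution_set(prof_r1, grid, 0.025)
  expect_true(all(band$band$lower <= sol$band$lower))
  expect_true(all(band$band$upper >= sol$band$upper))
})

test_that("in the zero-noise limit the Bonferroni band is the solution set", {
  m <- two_pool_model(100, 25)
  d <- two_pool_design()
  dat <- cbind(d, value = solve_model(m, c(r1 = 1, r2 = 0.5), d))
  f <- find_mle(dat, m, error_model("gaussian_additive"),
                lower = c(r1 = 0.01, r2 = 0.01), upper = c(r1 = 5, r2 = 5),
                start = c(r1 = 1, r2 = 0.5), fixed = c(sigma_N = 1e-6))
  p <- profile_parameter(f, "r1", 1 - 1e-5, 1 + 1e-5, n = 5)
  bon <- bonferroni_realization_set(p, grid, 0.05)
  sol <- suppressWarnings(solution_set(p, grid, 0.025))
  expect_equal(bon$band$lower, sol$band$lower, tolerance = 1e-4)
  expect_equal(bon$band$upper, sol$band$upper, tolerance = 1e-4)
})

test_that("bands on a coarse grid are restrictions of the fine-grid band", {
  fine_times <- seq(0, 2, length.out = 61)
  coarse_times <- fine_times[seq(1, 61, by = 4)]
  gf <- obs_design(fine_times, c("c1", "c2"))
  gc <- obs_design(coarse_times, c("c1", "c2"))
  bf <- solution_set(prof_r1, gf, 0.05)
  bc <- solution_set(prof_r1, gc, 0.05)
  shared <- bf$band$time %in% coarse_times
  expect_equal(bf$band$lower[shared], bc$band$lower, tolerance = 1e-12)
  expect_equal(bf$band$upper[shared], bc$band$upper, tolerance = 1e-12)
})

test_that("negativity flags fire for Gaussian bands and never for positive-support ones", {
  # Gaussian band about a trajectory that decays toward zero dips negative
  m0 <- exp_decay_model(100)
  d0 <- obs_design(seq(0, 6, length.out = 13))
  set.seed(40)
  dat0 <- cbind(d0, value = solve_model(m0, c(r1 = 1), d0) + rnorm(13, 0, 5))
  f0 <- find_mle(dat0, m0, error_model("gaussian_additive"),
                 lower = c(r1 = 0.01), upper = c(r1 = 5),
                 start = c(r1 = 1), fixed = c(sigma_N = 5))
  flags <- negativity_flag(mle_realization_set(f0, d0, 0.05))
  expect_true(any(flags))   # late-time mean near zero, 1.96 sigma dips below
  # Poisson and lognormal bands live on non-negative support
  m <- two_pool_model(100, 10)
  d <- obs_design(seq(0.5, 5, length.out = 10), c("c1", "c2"))
  set.seed(41)
  y <- solve_model(m, c(r1 = 1, r2 = 0.5), d)
  dat_ln <- cbind(d, value = y * rlnorm(length(y), 0, 0.4))
  f_ln <- find_mle(dat_ln, m, error_model("lognormal"),
                   lower = c(r1 = 0.01, r2 = 0.01, sigma_L = 0.01),
                   upper = c(r1 = 5, r2 = 5, sigma_L = 5),
                   start = c(r1 = 1, r2 = 0.5, sigma_L = 0.4))
  expect_false(any(negativity_flag(mle_realization_set(f_ln, d, 0.05))))
  dat_ps <- cbind(d, value = rpois(length(y), y))
  f_ps <- find_mle(dat_ps, m, error_model("poisson"),
                   lower = c(r1 = 0.01, r2 = 0.01),
                   upper = c(r1 = 5, r2 = 5), start = c(r1 = 1, r2 = 0.5))
  expect_false(any(negativity_flag(mle_realization_set(f_ps, d, 0.05))))
})

test_that("band-minus-MLE view is centred on zero for the MLE trajectory", {
  band <- solution_set(prof_r1, grid, 0.05)
  centred <- band_minus_mle(band, fit)
  expect_true(all(centred$lower <= 1e-9))
  expect_true(all(centred$upper >= -1e-9))
})
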