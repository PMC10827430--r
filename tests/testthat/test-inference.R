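test_that("log-likelihood has the additive structure of a sum over records", {
  m <- two_pool_model(100, 25)
  err <- error_model("gaussian_additive")
  set.seed(3)
  d <- two_pool_design(8)
  dat <- cbind(d, value = solve_model(m, c(r1 = 1, r2 = 0.5), d) +
                 rnorm(nrow(d), 0, 5))
  th <- c(r1 = 0.9, r2 = 0.6, sigma_N = 5)
  ll <- log_likelihood(th, dat, m, err)
  # duplicating every record doubles the value exactly
  expect_equal(log_likelihood(th, rbind(dat, dat), m, err), 2 * ll)
  # permuting observation order changes nothing
  perm <- dat[sample(nrow(dat)), ]
  expect_equal(log_likelihood(th, perm, m, err), ll)
})

test_that("Gaussian log-likelihood equals the closed-form residual expression", {
  m <- two_pool_model(100, 25)
  err <- error_model("gaussian_additive")
  set.seed(4)
  d <- two_pool_design()
  y <- solve_model(m, c(r1 = 1, r2 = 0.5), d)
  dat <- cbind(d, value = y + rnorm(length(y), 0, 5))
  th <- c(r1 = 1.05, r2 = 0.48, sigma_N = 4.4)
  yh <- solve_model(m, th[c("r1", "r2")], d)
  ssr <- sum((dat$value - yh)^2)
  I <- nrow(dat)
  expect_equal(log_likelihood(th, dat, m, err),
               -(I / 2) * log(2 * pi * 4.4^2) - ssr / (2 * 4.4^2),
               tolerance = 1e-10)
})

test_that("MLE recovers truth exactly from noiseless data", {
  dat <- noiseless_two_pool()
  m <- two_pool_model(100, 25)
  fit <- find_mle(dat, m, error_model("gaussian_additive"),
                  lower = c(r1 = 0.01, r2 = 0.01),
                  upper = c(r1 = 5, r2 = 5),
                  start = c(r1 = 0.7, r2 = 0.9), fixed = c(sigma_N = 5))
  expect_true(fit$converged)
  expect_equal(unname(fit$theta_hat[c("r1", "r2")]), c(1, 0.5),
               tolerance = 1e-4)
  # normalized log-likelihood is zero at the optimum by construction
  expect_equal(normalized_log_likelihood(fit$theta_hat, fit), 0)
  # and non-positive anywhere else
  expect_lte(normalized_log_likelihood(c(r1 = 1.1, r2 = 0.4, sigma_N = 5),
                                       fit), 1e-8)
})

test_that("MLE of a model linear in one scale parameter matches least squares", {
  m <- linear_scale_model()
  set.seed(9)
  d <- obs_design(seq(0, 3, length.out = 12))
  w <- exp(-d$time)
  dat <- cbind(d, value = 50 * w + rnorm(12, 0, 2))
  fit <- find_mle(dat, m, error_model("gaussian_additive"),
                  lower = c(A = 1), upper = c(A = 200),
                  start = c(A = 20), fixed = c(sigma_N = 2))
  # normal equations: A_hat = sum(w y) / sum(w^2)
  expect_equal(fit$theta_hat[["A"]], sum(w * dat$value) / sum(w^2),
               tolerance = 1e-6)
})

test_that("enlarging bounds already containing the MLE leaves it unchanged", {
  fit <- gaussian_two_pool_fit(seed = 21)
  wide <- find_mle(fit$data, fit$model, fit$err,
                   lower = c(r1 = 1e-4, r2 = 1e-4),
                   upper = c(r1 = 50, r2 = 50),
                   start = c(r1 = 1, r2 = 0.5), fixed = c(sigma_N = 5))
  expect_equal(wide$theta_hat[c("r1", "r2")],
               fit$theta_hat[c("r1", "r2")], tolerance = 1e-5)
})

test_that("lognormal MLE equals Gaussian MLE on log-transformed data", {
  m <- two_pool_model(100, 10)
  set.seed(14)
  d <- obs_design(seq(0, 5, length.out = 31), c("c1", "c2"))
  y <- solve_model(m, c(r1 = 1, r2 = 0.5), d)
  dat <- cbind(d, value = y * rlnorm(length(y), 0, 0.4))
  fit_ln <- find_mle(dat, m, error_model("lognormal"),
                     lower = c(r1 = 0.01, r2 = 0.01, sigma_L = 0.01),
                     upper = c(r1 = 5, r2 = 5, sigma_L = 5),
                     start = c(r1 = 1, r2 = 0.5, sigma_L = 0.4))
  # oracle route: a log-scale model with additive Gaussian errors on
  # log-observations shares the same objective up to the constant
  # sum(log y_obs), hence the same optimum for the shared parameters
  log_model <- pwa_model("log_two_pool", c("r1", "r2"), c("c1", "c2"),
                         c(c1_0 = 100, c2_0 = 10),
                         function(theta, design)
                           log(m$solve_fn(theta, design)))
  dat_log <- dat; dat_log$value <- log(dat$value)
  fit_g <- find_mle(dat_log, log_model, error_model("gaussian_additive"),
                    lower = c(r1 = 0.01, r2 = 0.01, sigma_N = 0.01),
                    upper = c(r1 = 5, r2 = 5, sigma_N = 5),
                    start = c(r1 = 1, r2 = 0.5, sigma_N = 0.4))
  expect_equal(fit_ln$theta_hat[c("r1", "r2")],
               fit_g$theta_hat[c("r1", "r2")], tolerance = 1e-4)
  expect_equal(fit_ln$theta_hat[["sigma_L"]], fit_g$theta_hat[["sigma_N"]],
               tolerance = 1e-4)
  expect_equal(fit_ln$loglik_hat, fit_g$loglik_hat - sum(dat_log$value),
               tolerance = 1e-6)
})

test_that("full-likelihood region: thresholds, MLE cell, and 1-d equivalence", {
  fit <- gaussian_two_pool_fit(seed = 33)
  reg <- full_likelihood_region(fit, alpha = 0.05, n_grid = 60)
  expect_equal(reg$threshold$value, -2.995732, tolerance = 1e-6)
  expect_equal(reg$threshold$df, 2)
  # the grid point nearest the MLE is always inside
  pts <- reg$points
  i <- which.min((pts$r1 - fit$theta_hat[["r1"]])^2 +
                 (pts$r2 - fit$theta_hat[["r2"]])^2)
  expect_true(pts$inside[i])
  expect_true(all(pts$loglik <= 1e-6))

  # single-parameter model: region endpoints match the profile CI
  # (no nuisance parameters, so the profile is the likelihood itself)
  m <- linear_scale_model()
  set.seed(2)
  d <- obs_design(seq(0, 3, length.out = 12))
  dat <- cbind(d, value = 50 * exp(-d$time) + rnorm(12, 0, 2))
  f1 <- find_mle(dat, m, error_model("gaussian_additive"),
                 lower = c(A = 1), upper = c(A = 200),
                 start = c(A = 40), fixed = c(sigma_N = 2))
  prof <- profile_parameter(f1, "A", 40, 60, n = 200)
  ci <- profile_ci(prof, 0.05)
  reg1 <- full_likelihood_region(f1, 0.05,
                                 grid = list(A = seq(40, 60, length.out = 4001)))
  inside_A <- reg1$points$A[reg1$points$inside]
  expect_equal(min(inside_A), ci$lower, tolerance = 1e-2)
  expect_equal(max(inside_A), ci$upper, tolerance = 1e-2)
})

test_that("degenerate optimisation inputs raise informative errors", {
  dat <- noiseless_two_pool()
  m <- two_pool_model(100, 25)
  err <- error_model("gaussian_additive")
  expect_error(find_mle(dat, m, err, lower = c(r1 = 1, r2 = 0.1),
                        upper = c(r1 = 0.5, r2 = 5),
                        start = c(r1 = 0.7, r2 = 1), fixed = c(sigma_N = 5)),
               "strictly below")
  expect_error(find_mle(dat, m, err, lower = c(r1 = 0.1, r2 = 0.1),
                        upper = c(r1 = 5, r2 = 5),
                        start = c(r1 = 9, r2 = 1), fixed = c(sigma_N = 5)),
               "outside bounds")
})
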