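# Shared fixtures built in code.

two_pool_design <- function(n = 16) {
  obs_design(seq(0, 2, length.out = n), c("c1", "c2"))
}

# Noiseless two-pool dataset at the canonical truth.
noiseless_two_pool <- function() {
  m <- two_pool_model(100, 25)
  d <- two_pool_design()
  cbind(d, value = solve_model(m, c(r1 = 1, r2 = 0.5), d))
}

# Gaussian two-pool dataset with seeded noise plus a fitted MLE
# (sigma_N fixed at 5), the workhorse fixture for profiling/prediction.
gaussian_two_pool_fit <- function(seed = 7, sigma = 5) {
  m <- two_pool_model(100, 25)
  err <- error_model("gaussian_additive")
  d <- two_pool_design()
  y <- solve_model(m, c(r1 = 1, r2 = 0.5), d)
  set.seed(seed)
  dat <- cbind(d, value = y + rnorm(length(y), 0, sigma))
  find_mle(dat, m, err,
           lower = c(r1 = 0.01, r2 = 0.01), upper = c(r1 = 5, r2 = 5),
           start = c(r1 = 1, r2 = 0.5), fixed = c(sigma_N = sigma))
}

# Single-parameter model linear in its scale parameter A: y(t) = A exp(-t).
# Conjugate Gaussian structure with closed-form MLE and exact quadratic
# profile, used as an analytic oracle.
linear_scale_model <- function() {
  pwa_model("linear_scale", "A", "c1", c(rate = 1),
            function(theta, design) theta[["A"]] * exp(-design$time))
}

# A synthetic profile object with prescribed mesh/values, for exercising
# interval extraction in isolation.
synthetic_profile <- function(mesh, values, psi_hat = mesh[which.max(values)]) {
  structure(list(interest = "psi", mesh = mesh, values = values,
                 nuisance = matrix(numeric(0), length(mesh), 0),
                 psi_hat = psi_hat, i_hat = which.max(values),
                 failed = rep(FALSE, length(mesh)), renormalized = FALSE,
                 bounds = range(mesh), fit = NULL),
            class = "pwa_profile")
}
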