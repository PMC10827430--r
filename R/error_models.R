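#' Measurement error models
#'
#' A measurement error model links a noise-free model solution `y_i(theta)`
#' to an observation `y^o_i`.  Three models are provided:
#' \describe{
#'   \item{`gaussian_additive`}{`y^o | theta ~ N(y, sigma_N^2)`; noise
#'     parameter `sigma_N > 0`.  Mean, median and mode all equal `y`;
#'     negative observations are admissible by design (no clipping) — lower
#'     band edges below zero are a diagnostic signal, not an error.}
#'   \item{`lognormal`}{multiplicative, `y^o | theta ~ LogNormal(log y,
#'     sigma_L^2)`; noise parameter `sigma_L > 0`.  The median is `y`, the
#'     mean `y exp(sigma_L^2 / 2)`; support is the positive half-line.}
#'   \item{`poisson`}{`y^o | theta ~ Pois(y)` with no extra noise
#'     parameters; observations must be non-negative integers while `y` may
#'     take any non-negative value.  At `y = 0` the limiting distribution is
#'     a point mass at zero.}
#' }
#'
#' @param name one of `"gaussian_additive"`, `"lognormal"`, `"poisson"`.
#' @return object of class `pwa_error` with fields `name` and
#'   `noise_params` (ordered labels of the error parameters, empty for
#'   Poisson).
#' @examples
#' err_log_density(error_model("gaussian_additive"), 100, 100, c(sigma_N = 1))
#' @export
error_model <- function(name = c("gaussian_additive", "lognormal", "poisson")) {
  name <- match.arg(name)
  noise_params <- switch(name,
    gaussian_additive = "sigma_N",
    lognormal = "sigma_L",
    poisson = character(0))
  structure(list(name = name, noise_params = noise_params),
            class = "pwa_error")
}

#' @export
print.pwa_error <- function(x, ...) {
  cat("<pwa_error> ", x$name,
      if (length(x$noise_params))
        paste0(" (noise parameters: ",
               paste(x$noise_params, collapse = ", "), ")")
      else " (no noise parameters)", "\n", sep = "")
  invisible(x)
}

check_noise_params <- function(err, theta_e) {
  if (length(err$noise_params) == 0L) return(numeric(0))
  th <- theta_e[err$noise_params]
  if (anyNA(th)) stop("missing noise parameters: ",
                      paste(err$noise_params, collapse = ", "))
  if (any(th <= 0)) stop("noise parameters must be positive")
  th
}

#' Log-density of observations under an error model
#'
#' Vectorised over `y_obs` and `y`.  Support violations that are legitimate
#' parameter-dependent events during optimisation (a positive observation
#' where the fitted trajectory is zero, a Poisson count above a zero mean)
#' return `-Inf`; structurally impossible inputs (non-positive lognormal
#' observations, non-integer Poisson counts) are errors.
#'
#' @param err an [error_model()].
#' @param y_obs observed values.
#' @param y noise-free model solution values.
#' @param theta_e named numeric vector of noise parameters (ignored for
#'   Poisson).
#' @return numeric vector of log-densities (log-probabilities for Poisson).
#' @export
err_log_density <- function(err, y_obs, y, theta_e = numeric(0)) {
  stopifnot(inherits(err, "pwa_error"), length(y_obs) == length(y) ||
              length(y_obs) == 1L || length(y) == 1L)
  th <- check_noise_params(err, theta_e)
  switch(err$name,
    gaussian_additive = stats::dnorm(y_obs, mean = y, sd = th[[1L]], log = TRUE),
    lognormal = {
      if (any(y_obs <= 0)) stop("lognormal observations must be positive")
      # fitted solution exactly 0 with a positive observation: -Inf by convention
      ld <- stats::dlnorm(y_obs, meanlog = log(pmax(y, .Machine$double.xmin)),
                          sdlog = th[[1L]], log = TRUE)
      ld[rep_len(y <= 0, length(ld))] <- -Inf
      ld
    },
    poisson = {
      if (any(y_obs < 0) || any(y_obs != round(y_obs)))
        stop("Poisson observations must be non-negative integers")
      if (any(y < 0)) stop("Poisson mean must be non-negative")
      # dpois handles lambda = 0 as the point-mass limit: 0 if x = 0 else -Inf
      stats::dpois(y_obs, lambda = y, log = TRUE)
    })
}

#' Quantile of the observation distribution
#'
#' @param err an [error_model()].
#' @param p probability in (0, 1); vectorised.
#' @param y noise-free model solution value(s).
#' @param theta_e named noise parameters.
#' @return quantiles on the observation scale.  Gaussian:
#'   `y + sigma_N * qnorm(p)`; lognormal: `exp(log y + sigma_L * qnorm(p))`;
#'   Poisson: smallest integer `k` with `CDF(k; y) >= p` (0 for all `p` when
#'   `y = 0`).
#' @export
err_quantile <- function(err, p, y, theta_e = numeric(0)) {
  stopifnot(inherits(err, "pwa_error"))
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly inside (0, 1)")
  th <- check_noise_params(err, theta_e)
  switch(err$name,
    gaussian_additive = y + th[[1L]] * stats::qnorm(p),
    lognormal = {
      if (any(y <= 0)) stop("lognormal requires positive model solutions")
      exp(log(y) + th[[1L]] * stats::qnorm(p))
    },
    poisson = stats::qpois(p, lambda = y))
}

#' Draw synthetic measurements
#'
#' I.i.d. draws from the observation distribution about each solution value,
#' using R's current (caller-seeded) random number stream.
#'
#' @param err an [error_model()].
#' @param y vector of noise-free solution values.
#' @param theta_e named noise parameters.
#' @return numeric vector of synthetic measurements, one per element of `y`.
#' @export
err_sample <- function(err, y, theta_e = numeric(0)) {
  stopifnot(inherits(err, "pwa_error"))
  th <- check_noise_params(err, theta_e)
  n <- length(y)
  switch(err$name,
    gaussian_additive = stats::rnorm(n, mean = y, sd = th[[1L]]),
    lognormal = {
      if (any(y <= 0)) stop("lognormal requires positive model solutions")
      stats::rlnorm(n, meanlog = log(y), sdlog = th[[1L]])
    },
    poisson = stats::rpois(n, lambda = y))
}

#' Residuals and ratios against a fitted trajectory
#'
#' Additive residuals `y^o - y(theta_hat)` or multiplicative ratios
#' `y^o / y(theta_hat)` (the natural diagnostic under the lognormal model;
#' requires strictly positive fitted values).
#'
#' @param data dataset (columns `time`\[, `position`\], `species`, `value`).
#' @param fitted fitted solution values aligned with the rows of `data`.
#' @param kind `"additive"` or `"ratio"`.
#' @return object of class `pwa_residuals`: list with `values` and `kind`.
#' @export
residual_set <- function(data, fitted, kind = c("additive", "ratio")) {
  kind <- match.arg(kind)
  if (length(fitted) != nrow(data))
    stop("fitted values (", length(fitted), ") not aligned with data rows (",
         nrow(data), ")")
  values <- if (kind == "additive") data$value - fitted
            else {
              if (any(fitted <= 0))
                stop("ratio residuals need strictly positive fitted values")
              data$value / fitted
            }
  structure(list(values = values, kind = kind), class = "pwa_residuals")
}

#' Quantile--quantile points for residual diagnostics
#'
#' Sorted residuals paired with reference quantiles at plotting positions
#' `(i - 0.5) / n`.  The reference is a normal distribution fitted to the
#' residuals (for additive residuals) or a lognormal with median 1 fitted to
#' log-ratios (for ratio residuals); points falling on the identity line
#' support the corresponding error model.
#'
#' @param residuals a [residual_set()].
#' @param reference `"normal"` or `"lognormal"`.
#' @return data frame with columns `theoretical` and `observed`.
#' @export
qq_points <- function(residuals, reference = c("normal", "lognormal")) {
  stopifnot(inherits(residuals, "pwa_residuals"))
  reference <- match.arg(reference)
  v <- sort(residuals$values)
  n <- length(v)
  if (n < 2L) stop("need at least two residuals")
  p <- (seq_len(n) - 0.5) / n
  theoretical <- if (reference == "normal") {
    stats::qnorm(p, mean = mean(v), sd = stats::sd(v))
  } else {
    if (any(v <= 0)) stop("lognormal reference needs positive ratios")
    stats::qlnorm(p, meanlog = 0, sdlog = stats::sd(log(v)))
  }
  data.frame(theoretical = theoretical, observed = v)
}

# Registry used by JSON configs.
error_registry <- function(name) {
  error_model(switch(name,
    gaussian_additive = , gaussian = "gaussian_additive",
    lognormal = "lognormal",
    poisson = "poisson",
    stop("unknown error model '", name, "'")))
}
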