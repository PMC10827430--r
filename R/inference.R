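# Likelihood assembly and maximum-likelihood estimation.
#
# The full parameter vector is theta = (theta_M, theta_E): mechanistic
# parameters in the model's declared order followed by the error model's
# noise parameters.  Any subset may be held fixed at known values (e.g. a
# pre-specified sigma_N); the remaining free parameters are estimated under
# box constraints.

full_param_names <- function(model, err) c(model$params, err$noise_params)

# Large negative sentinel returned in place of -Inf/NaN so simplex moves
# stay finite; any admissible point dominates it.
.neg_sentinel <- -1e10

# Builds a fast closure over raw vectors: free parameter values in, total
# log-likelihood out.  All data-frame handling happens once, here.
make_loglik <- function(data, model, err, fixed = numeric(0)) {
  all_names <- full_param_names(model, err)
  if (length(fixed) && !all(names(fixed) %in% all_names))
    stop("fixed entries not among parameters: ",
         paste(setdiff(names(fixed), all_names), collapse = ", "))
  free_names <- setdiff(all_names, names(fixed))
  design <- data[, setdiff(names(data), "value"), drop = FALSE]
  obs <- data$value
  template <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  template[names(fixed)] <- unlist(fixed)
  m_names <- model$params
  e_names <- err$noise_params
  fn <- function(free_values) {
    theta <- template
    theta[free_names] <- free_values
    y <- tryCatch(model$solve_fn(theta[m_names], design),
                  error = function(e) NULL)
    if (is.null(y)) return(.neg_sentinel)
    ll <- sum(err_log_density(err, obs, y, theta[e_names]))
    if (!is.finite(ll)) .neg_sentinel else ll
  }
  attr(fn, "free_names") <- free_names
  attr(fn, "template") <- template
  fn
}

#' Log-likelihood of the full model
#'
#' Sum over observations of the log-density of each measurement under the
#' error model, evaluated about the mechanistic model solution:
#' `l(theta | y^o) = sum_i log phi(y^o_i; y_i(theta), theta)`.
#'
#' @param theta named numeric vector covering all mechanistic and noise
#'   parameters.
#' @param data dataset with columns `time`\[, `position`\], `species`,
#'   `value`.
#' @param model a [pwa_model()].
#' @param err an [error_model()].
#' @return scalar log-likelihood; `-Inf` when the data fall outside the
#'   observation support at `theta`.
#' @export
log_likelihood <- function(theta, data, model, err) {
  design <- data[, setdiff(names(data), "value"), drop = FALSE]
  y <- solve_model(model, theta[model$params], design)
  sum(err_log_density(err, data$value, y, theta[err$noise_params]))
}

#' Normalized log-likelihood
#'
#' `l(theta) - l(theta_hat)`, so the surface has maximum 0 at the MLE.
#'
#' @param theta named full parameter vector.
#' @param fit a [find_mle()] result on the same data/model/error model.
#' @return scalar <= 0 (up to optimiser tolerance).
#' @export
normalized_log_likelihood <- function(theta, fit) {
  log_likelihood(theta, fit$data, fit$model, fit$err) - fit$loglik_hat
}

# Map box-constrained x to unbounded u and back (scaled logit); keeps the
# simplex search inside bounds without hard rejections.
box_to_u <- function(x, l, u) stats::qlogis(pmin(pmax((x - l) / (u - l), 1e-10), 1 - 1e-10))
u_to_box <- function(v, l, u) l + (u - l) * stats::plogis(v)

#' Maximum-likelihood estimation under box constraints
#'
#' Maximises the joint log-likelihood of mechanistic and noise parameters by
#' a derivative-free simplex search on a logit-transformed box (robust to
#' the `-Inf` plateaus of support-restricted error models), optionally
#' followed by a bounded quasi-Newton refinement.  Additional Latin
#' hypercube restarts can be requested; the best converged optimum wins.
#'
#' @param data dataset.
#' @param model a [pwa_model()].
#' @param err an [error_model()].
#' @param lower,upper named numeric bounds for the free parameters.
#' @param start named numeric starting point (within bounds).
#' @param fixed named numeric vector of parameters held at known values.
#' @param n_starts total number of starts (1 = just `start`; extra starts
#'   are Latin hypercube draws over the box, requires the `lhs` package).
#' @param refine logical: attempt an `L-BFGS-B` polish of the simplex
#'   optimum.
#' @param reltol simplex relative convergence tolerance on the objective.
#' @return object of class `pwa_fit`: the MLE `theta_hat` (full vector,
#'   fixed entries included), `loglik_hat`, `converged`, `n_evals`, bounds
#'   and the inputs (carried for profiling and prediction).
#' @examples
#' m <- two_pool_model(100, 25)
#' d <- obs_design(seq(0, 2, length.out = 16), c("c1", "c2"))
#' dat <- cbind(d, value = solve_model(m, c(r1 = 1, r2 = 0.5), d))
#' fit <- find_mle(dat, m, error_model("gaussian_additive"),
#'                 lower = c(r1 = 0.01, r2 = 0.01),
#'                 upper = c(r1 = 5, r2 = 5),
#'                 start = c(r1 = 0.8, r2 = 0.8), fixed = c(sigma_N = 5))
#' @export
find_mle <- function(data, model, err, lower, upper, start,
                     fixed = numeric(0), n_starts = 1L, refine = TRUE,
                     reltol = 1e-9) {
  ll <- make_loglik(data, model, err, fixed)
  free <- attr(ll, "free_names")
  l <- lower[free]; u <- upper[free]
  if (anyNA(l) || anyNA(u)) stop("bounds must cover all free parameters")
  if (any(l >= u)) stop("lower bounds must be strictly below upper bounds")
  s0 <- start[free]
  if (anyNA(s0)) stop("start must cover all free parameters")
  if (any(s0 < l | s0 > u)) stop("start outside bounds")

  starts <- list(s0)
  if (n_starts > 1L) {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("package 'lhs' is needed for multi-start fitting")
    hyp <- lhs::randomLHS(n_starts - 1L, length(free))
    for (i in seq_len(n_starts - 1L))
      starts[[i + 1L]] <- stats::setNames(l + (u - l) * hyp[i, ], free)
  }

  if (length(free) == 1L) {
    # one free parameter: golden-section/parabolic search on the box
    res <- stats::optimize(function(x) ll(stats::setNames(x, free)),
                           lower = l, upper = u, maximum = TRUE,
                           tol = 1e-10)
    cand <- stats::setNames(res$maximum, free)
    v_start <- ll(s0)
    if (v_start > res$objective) { cand <- s0; res$objective <- v_start }
    theta_hat <- attr(ll, "template")
    theta_hat[free] <- cand
    return(structure(list(theta_hat = theta_hat,
                          loglik_hat = res$objective, converged = TRUE,
                          n_evals = NA_integer_, free_names = free,
                          fixed = fixed, lower = l, upper = u,
                          data = data, model = model, err = err,
                          loglik_fn = ll),
                     class = "pwa_fit"))
  }

  neg_obj_u <- function(v) -ll(u_to_box(v, l, u))
  best <- NULL; n_evals <- 0L; failures <- character(0)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(box_to_u(s, l, u), neg_obj_u, method = "Nelder-Mead",
                   control = list(maxit = 5000L, reltol = reltol)),
      error = function(e) e)
    if (inherits(res, "error")) { failures <- c(failures, conditionMessage(res)); next }
    n_evals <- n_evals + res$counts[1L]
    cand <- list(par = u_to_box(res$par, l, u), value = -res$value,
                 converged = res$convergence == 0L)
    if (is.null(best) || cand$value > best$value) best <- cand
  }
  if (is.null(best))
    stop("all optimisation starts failed: ",
         paste(unique(failures), collapse = "; "))

  if (refine) {
    pol <- tryCatch(
      stats::optim(best$par, function(x) -ll(x), method = "L-BFGS-B",
                   lower = l, upper = u,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(pol) && -pol$value > best$value) {
      n_evals <- n_evals + pol$counts[1L]
      best <- list(par = pol$par, value = -pol$value, converged = TRUE)
    }
  }

  theta_hat <- attr(ll, "template")
  theta_hat[free] <- best$par
  structure(list(theta_hat = theta_hat, loglik_hat = best$value,
                 converged = best$converged, n_evals = n_evals,
                 free_names = free, fixed = fixed,
                 lower = l, upper = u,
                 data = data, model = model, err = err, loglik_fn = ll),
            class = "pwa_fit")
}

#' @export
print.pwa_fit <- function(x, ...) {
  cat("<pwa_fit> ", x$model$name, " + ", x$err$name, "\n", sep = "")
  cat("  log-likelihood at MLE:", format(x$loglik_hat, digits = 8), "\n")
  cat("  MLE:", paste(names(x$theta_hat), signif(x$theta_hat, 4),
                      sep = " = ", collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), collapse = ", "), "\n")
  cat("  converged:", x$converged, " (", x$n_evals, "evaluations )\n")
  invisible(x)
}

# Observed-information standard errors of the free parameters; returns NULL
# when the Hessian is not usable.  Used to auto-scale profile meshes and
# region grids.
fit_standard_errors <- function(fit) {
  free <- fit$free_names
  H <- tryCatch(stats::optimHess(fit$theta_hat[free], fit$loglik_fn),
                error = function(e) NULL)
  if (is.null(H)) return(NULL)
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  v <- diag(as.matrix(cov))
  if (any(!is.finite(v) | v <= 0)) return(NULL)
  stats::setNames(sqrt(v), free)
}

# Log-likelihood at every row of a free-parameter matrix.  Uses the model's
# vectorised solver when available and all noise parameters are fixed;
# otherwise falls back to a row loop.
loglik_over_grid <- function(fit, theta_mat) {
  free <- fit$free_names
  model <- fit$model; err <- fit$err
  noise_free <- intersect(err$noise_params, free)
  if (!is.null(model$solve_grid_fn) && length(noise_free) == 0L &&
      all(colnames(theta_mat) %in% model$params)) {
    design <- fit$data[, setdiff(names(fit$data), "value"), drop = FALSE]
    pred <- solve_model_grid(model, theta_mat, design)
    obs <- matrix(fit$data$value, nrow = nrow(pred), ncol = ncol(pred),
                  byrow = TRUE)
    theta_e <- attr(fit$loglik_fn, "template")[err$noise_params]
    ld <- err_log_density(err, obs, pred, theta_e)
    ll <- rowSums(ld)
    ll[!is.finite(ll)] <- .neg_sentinel
    ll
  } else {
    apply(theta_mat, 1L, fit$loglik_fn)
  }
}

#' Full-likelihood confidence region on a grid
#'
#' Gold-standard baseline for low-dimensional problems: evaluates the
#' normalized log-likelihood on a tensor grid of the free parameters and
#' keeps the points at or above the chi-square threshold with degrees of
#' freedom equal to the number of free parameters,
#' `l_hat(theta) >= -Delta_{nu,1-alpha} / 2`.
#'
#' @param fit a [find_mle()] result with at most 3 free parameters.
#' @param alpha significance level (default 0.05 for a 95\% region).
#' @param grid optional named list of per-parameter mesh vectors; defaults
#'   to `n_grid` equally spaced points across the fit's box bounds.
#' @param n_grid default per-parameter grid size.
#' @return object of class `pwa_region`: data frame `points` (grid
#'   coordinates, normalized log-likelihood, `inside` flag), the
#'   [loglik_threshold()] used, and `alpha`.
#' @export
full_likelihood_region <- function(fit, alpha = 0.05, grid = NULL,
                                   n_grid = 200L) {
  free <- fit$free_names
  nu <- length(free)
  if (nu > 3L) stop("grid region supported for at most 3 free parameters")
  if (is.null(grid))
    grid <- stats::setNames(lapply(free, function(p)
      seq(fit$lower[[p]], fit$upper[[p]], length.out = n_grid)), free)
  if (!all(free %in% names(grid))) stop("grid must name every free parameter")
  pts <- as.matrix(expand.grid(grid[free], KEEP.OUT.ATTRS = FALSE))
  ll <- loglik_over_grid(fit, pts) - fit$loglik_hat
  thr <- loglik_threshold(alpha, nu)
  inside <- ll >= thr$value
  if (!any(inside))
    stop("empty region: grid too coarse or misplaced (max normalized ",
         "log-likelihood on grid = ", format(max(ll), digits = 4), ")")
  points <- as.data.frame(pts)
  points$loglik <- ll
  points$inside <- inside
  structure(list(points = points, threshold = thr, alpha = alpha,
                 free_names = free),
            class = "pwa_region")
}

#' @export
print.pwa_region <- function(x, ...) {
  cat("<pwa_region> ", 100 * (1 - x$alpha), "% full-likelihood region, ",
      sum(x$points$inside), " of ", nrow(x$points),
      " grid points inside (threshold ",
      format(x$threshold$value, digits = 6), ")\n", sep = "")
  invisible(x)
}
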