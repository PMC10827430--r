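# Confidence bands for model solutions and for noisy data realizations.
#
# All bands are stored as pointwise lower/upper envelopes on a prediction
# grid: the underlying sets are unions of curves, and the envelope is the
# computable representation used for plotting and for containment tests.

new_band <- function(grid, lower, upper, level, kind, source) {
  stopifnot(length(lower) == nrow(grid), length(upper) == nrow(grid))
  if (any(lower > upper + 1e-12)) stop("band has lower > upper")
  df <- cbind(grid, lower = lower, upper = upper)
  structure(list(band = df, level = level, kind = kind, source = source),
            class = "pwa_band")
}

#' @export
print.pwa_band <- function(x, ...) {
  cat("<pwa_band> ", x$kind, " set, level ", x$level, ", source '",
      x$source, "', ", nrow(x$band), " grid points\n", sep = "")
  invisible(x)
}

#' Default prediction grid
#'
#' Equally spaced times spanning a dataset's observation window, finer than
#' the data (default 100 points), expanded over the model's species.
#'
#' @param data dataset whose time span to cover.
#' @param model the [pwa_model()] providing species labels.
#' @param n number of time points.
#' @return an [obs_design()] data frame.
#' @export
prediction_grid <- function(data, model, n = 100L) {
  obs_design(seq(min(data$time), max(data$time), length.out = n),
             model$species)
}

# theta rows for the mesh points of `profile` whose profile value reaches
# the threshold at the given alpha; the MLE row is always included.
profile_theta_rows <- function(profile, alpha) {
  fit <- profile$fit
  lc <- loglik_threshold(alpha, 1L)$value
  keep <- which(!is.na(profile$values) & profile$values >= lc)
  free <- fit$free_names
  mat <- matrix(NA_real_, length(keep) + 1L, length(free),
                dimnames = list(NULL, free))
  nuis <- colnames(profile$nuisance)
  for (j in seq_along(keep)) {
    mat[j, profile$interest] <- profile$mesh[keep[j]]
    mat[j, nuis] <- profile$nuisance[keep[j], ]
  }
  mat[length(keep) + 1L, ] <- fit$theta_hat[free]
  mat
}

# Completes free-parameter rows with fixed values and returns the
# trajectory matrix (rows = parameter vectors) on the grid.
trajectories_on_grid <- function(fit, theta_free_mat, grid) {
  template <- attr(fit$loglik_fn, "template")
  full <- matrix(template, nrow(theta_free_mat), length(template),
                 byrow = TRUE, dimnames = list(NULL, names(template)))
  full[, colnames(theta_free_mat)] <- theta_free_mat
  solve_model_grid(fit$model, full, grid)
}

#' Profile-wise confidence set for the model solution
#'
#' Propagates uncertainty in one interest parameter into the model solution:
#' the mechanistic model is simulated at `(psi, lambda*(psi))` for every
#' profile mesh point inside the level `1 - alpha` confidence interval
#' (MLE trajectory always included), and the band is the pointwise min/max
#' envelope of those trajectories.  Profiling a pure noise parameter yields
#' a zero-width band: the deterministic solution does not depend on it.
#'
#' @param profile a [profile_parameter()] result.
#' @param grid prediction design ([prediction_grid()] or any
#'   [obs_design()]).
#' @param alpha significance level (default 0.05).
#' @return a `pwa_band` of kind `"solution"`.
#' @export
solution_set <- function(profile, grid, alpha = 0.05) {
  stopifnot(inherits(profile, "pwa_profile"), nrow(grid) > 0L)
  th <- profile_theta_rows(profile, alpha)
  if (nrow(th) < 3L)  # interior mesh points + MLE row
    warning("fewer than 2 mesh points inside the confidence interval; ",
            "the band collapses toward the MLE trajectory and understates ",
            "uncertainty")
  traj <- trajectories_on_grid(profile$fit, th, grid)
  new_band(grid, apply(traj, 2L, min), apply(traj, 2L, max),
           level = 1 - alpha, kind = "solution", source = profile$interest)
}

#' Union of confidence bands
#'
#' Pointwise union: min of the lower envelopes, max of the uppers.  Inputs
#' must share the same grid, level and kind; the union of profile-wise sets
#' over all parameters treated in turn is the standard conservative
#' composite.
#'
#' @param bands list of `pwa_band` objects.
#' @return a `pwa_band` with source `"union"`.
#' @export
union_bands <- function(bands) {
  stopifnot(length(bands) >= 1L, all(vapply(bands, inherits, TRUE, "pwa_band")))
  b1 <- bands[[1L]]
  gcols <- setdiff(names(b1$band), c("lower", "upper"))
  for (b in bands[-1L]) {
    if (!identical(b$band[gcols], b1$band[gcols]))
      stop("bands must share an identical prediction grid")
    if (!identical(b$level, b1$level) || !identical(b$kind, b1$kind))
      stop("bands must share level and kind")
  }
  lo <- do.call(pmin, lapply(bands, function(b) b$band$lower))
  hi <- do.call(pmax, lapply(bands, function(b) b$band$upper))
  new_band(b1$band[gcols], lo, hi, b1$level, b1$kind, "union")
}

#' MLE-based confidence set for data realizations
#'
#' Treats the MLE as the truth: at each grid point the band is the
#' `[alpha/2, 1 - alpha/2]` quantile interval of the error distribution
#' about the MLE trajectory.  Simple, but does not account for parameter
#' uncertainty, so it can undercover when the MLE is far from the truth.
#'
#' @param fit a [find_mle()] result.
#' @param grid prediction design.
#' @param alpha significance level.
#' @return a `pwa_band` of kind `"realization"`, source `"mle"`.
#' @export
mle_realization_set <- function(fit, grid, alpha = 0.05) {
  stopifnot(inherits(fit, "pwa_fit"))
  y <- solve_model(fit$model, fit$theta_hat[fit$model$params], grid)
  theta_e <- fit$theta_hat[fit$err$noise_params]
  new_band(grid,
           err_quantile(fit$err, alpha / 2, y, theta_e),
           err_quantile(fit$err, 1 - alpha / 2, y, theta_e),
           level = 1 - alpha, kind = "realization", source = "mle")
}

#' Bonferroni-corrected profile-wise confidence set for data realizations
#'
#' Splits the error budget between parameter and observation uncertainty:
#' the profile-wise solution set is taken at level `1 - alpha/2`, and
#' around every trajectory in it a pointwise `[alpha/4, 1 - alpha/4]`
#' quantile band of the error distribution is drawn; the returned band is
#' the union (envelope) over trajectories.  Conservative by construction.
#'
#' @param profile a [profile_parameter()] result whose mesh extends past
#'   the level `1 - alpha/2` interval.
#' @param grid prediction design.
#' @param alpha overall significance level.
#' @return a `pwa_band` of kind `"realization"`.
#' @export
bonferroni_realization_set <- function(profile, grid, alpha = 0.05) {
  stopifnot(inherits(profile, "pwa_profile"))
  fit <- profile$fit
  th <- profile_theta_rows(profile, alpha / 2)
  traj <- trajectories_on_grid(fit, th, grid)
  template <- attr(fit$loglik_fn, "template")
  e_names <- fit$err$noise_params
  lo <- hi <- NULL
  for (j in seq_len(nrow(th))) {
    theta_e <- template[e_names]
    theta_e[intersect(e_names, colnames(th))] <-
      th[j, intersect(e_names, colnames(th))]
    l <- err_quantile(fit$err, alpha / 4, traj[j, ], theta_e)
    h <- err_quantile(fit$err, 1 - alpha / 4, traj[j, ], theta_e)
    lo <- if (is.null(lo)) l else pmin(lo, l)
    hi <- if (is.null(hi)) h else pmax(hi, h)
  }
  new_band(grid, lo, hi, level = 1 - alpha, kind = "realization",
           source = profile$interest)
}

# Free-parameter rows of a full-likelihood region recomputed at `alpha`
# (the region's grid stores normalized log-likelihoods, so any level at or
# above the region's own can be sliced without re-evaluation).
region_theta_rows <- function(fit, region, alpha) {
  thr <- loglik_threshold(alpha, region$threshold$df)$value
  pts <- region$points
  keep <- pts$loglik >= thr
  mat <- as.matrix(pts[keep, region$free_names, drop = FALSE])
  rbind(mat, fit$theta_hat[region$free_names])
}

#' Solution confidence set from a full-likelihood region
#'
#' Envelope of model trajectories over every grid point of a
#' [full_likelihood_region()] at or above the chi-square threshold at level
#' `1 - alpha` (degrees of freedom = number of free parameters).  The
#' gold-standard counterpart of [solution_set()].
#'
#' @param fit the [find_mle()] result the region was built from.
#' @param region a [full_likelihood_region()].
#' @param grid prediction design.
#' @param alpha significance level; must be >= the region's own alpha so
#'   the stored grid still covers the set.
#' @return a `pwa_band` of kind `"solution"`, source `"full_likelihood"`.
#' @export
region_solution_set <- function(fit, region, grid, alpha = 0.05) {
  stopifnot(inherits(region, "pwa_region"))
  th <- region_theta_rows(fit, region, alpha)
  traj <- trajectories_on_grid(fit, th, grid)
  new_band(grid, apply(traj, 2L, min), apply(traj, 2L, max),
           level = 1 - alpha, kind = "solution", source = "full_likelihood")
}

#' Bonferroni realization set from a full-likelihood region
#'
#' As [bonferroni_realization_set()], with the level `1 - alpha/2` solution
#' set taken from the full-likelihood grid region instead of a single
#' profile.
#'
#' @inheritParams region_solution_set
#' @return a `pwa_band` of kind `"realization"`, source
#'   `"full_likelihood"`.
#' @export
region_realization_set <- function(fit, region, grid, alpha = 0.05) {
  stopifnot(inherits(region, "pwa_region"))
  th <- region_theta_rows(fit, region, alpha / 2)
  traj <- trajectories_on_grid(fit, th, grid)
  theta_e <- fit$theta_hat[fit$err$noise_params]
  lo <- apply(err_quantile(fit$err, alpha / 4, traj, theta_e), 2L, min)
  hi <- apply(err_quantile(fit$err, 1 - alpha / 4, traj, theta_e), 2L, max)
  new_band(grid, lo, hi, level = 1 - alpha, kind = "realization",
           source = "full_likelihood")
}

#' Non-physical (negative) prediction flag
#'
#' Flags, per species, whether a band's lower envelope dips below zero
#' anywhere on the grid.  For concentrations and densities this is the
#' tell-tale of a misspecified additive Gaussian error model; bands built
#' under Poisson or lognormal error models are non-negative by construction.
#'
#' @param band a `pwa_band`.
#' @return named logical vector, one entry per species.
#' @export
negativity_flag <- function(band) {
  stopifnot(inherits(band, "pwa_band"))
  tapply(band$band$lower, band$band$species, function(v) any(v < 0))[
    unique(band$band$species)]
}

#' Band relative to the MLE trajectory
#'
#' Convenience output transform: subtracts the MLE trajectory from a band's
#' envelopes, the difference-from-MLE view used to inspect narrow bands.
#'
#' @param band a `pwa_band`.
#' @param fit the [find_mle()] result providing the MLE trajectory.
#' @return data frame with the grid columns and centred `lower`/`upper`.
#' @export
band_minus_mle <- function(band, fit) {
  grid <- band$band[, setdiff(names(band$band), c("lower", "upper")),
                    drop = FALSE]
  y <- solve_model(fit$model, fit$theta_hat[fit$model$params], grid)
  out <- grid
  out$lower <- band$band$lower - y
  out$upper <- band$band$upper - y
  out
}
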