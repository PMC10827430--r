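# Repeated-sampling evaluation of observed coverage for parameter
# confidence intervals and for solution / realization confidence sets.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Define a coverage study
#'
#' Bundles everything the repeated-sampling machinery needs: the data
#' generating process (model, error model, true parameters, observation
#' design), the estimation set-up (bounds, fixed parameters), the grids on
#' which sets are evaluated, and a base seed so that every replicate is
#' deterministically replayable (replicate `r` draws with seed
#' `base_seed + r`; the independent replication stream for realization
#' tests uses `base_seed + 1e6 + r`).
#'
#' The default arguments reproduce the two-pool linear study: additive
#' Gaussian noise with `sigma_N = 5` fixed and known, true rates
#' `(r1, r2) = (1.0, 0.5)`, initial concentrations `(100, 25)`, both
#' species observed at 16 equally spaced times in `[0, 2]`; the solution
#' truth grid is 100 equally spaced times on `[0.022, 2.200]` (`t = 0` is
#' excluded because initial conditions are fixed known quantities) and the
#' realization test design is 15 equally spaced times on `[0.13, 2.00]`.
#'
#' @param base_seed integer reproducibility anchor (required).
#' @param model,err data-generating [pwa_model()] and [error_model()].
#' @param theta_true named true full parameter vector.
#' @param design observation design for each synthetic dataset.
#' @param fixed named parameters held at known values during estimation.
#' @param lower,upper estimation box bounds for the free parameters.
#' @param truth_grid times at which solution-set coverage is evaluated.
#' @param test_times times of the fresh replicate dataset used to test
#'   realization sets.
#' @return object of class `pwa_study`.
#' @export
coverage_study <- function(base_seed,
                           model = two_pool_model(100, 25),
                           err = error_model("gaussian_additive"),
                           theta_true = c(r1 = 1.0, r2 = 0.5, sigma_N = 5.0),
                           design = obs_design(seq(0, 2, length.out = 16),
                                               c("c1", "c2")),
                           fixed = c(sigma_N = 5.0),
                           lower = c(r1 = 0.01, r2 = 0.01),
                           upper = c(r1 = 5, r2 = 5),
                           truth_grid = seq(0.022, 2.200, length.out = 100),
                           test_times = seq(0.13, 2.00, length.out = 15)) {
  if (missing(base_seed) || is.null(base_seed) || !is.finite(base_seed))
    stop("coverage studies require an explicit base_seed ",
         "(reproducibility contract)")
  structure(list(base_seed = as.integer(base_seed), model = model, err = err,
                 theta_true = theta_true, design = design, fixed = fixed,
                 lower = lower, upper = upper, truth_grid = truth_grid,
                 test_times = test_times),
            class = "pwa_study")
}

#' @export
print.pwa_study <- function(x, ...) {
  cat("<pwa_study> ", x$model$name, " + ", x$err$name, ", ",
      nrow(x$design), " observations/replicate, base seed ",
      x$base_seed, "\n", sep = "")
  cat("  truth: ", paste(names(x$theta_true), x$theta_true, sep = " = ",
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate one replicate dataset of a coverage study
#'
#' @param study a [coverage_study()].
#' @param rep replicate index (>= 1).
#' @param stream `"primary"` for the estimation dataset, `"replicate"` for
#'   the independent fresh dataset (offset seed stream) drawn at
#'   `test_times` for realization-set testing.
#' @return dataset data frame (design columns + `value`).
#' @export
simulate_dataset <- function(study, rep, stream = c("primary", "replicate")) {
  stream <- match.arg(stream)
  design <- if (stream == "primary") study$design
            else obs_design(study$test_times, study$model$species)
  y <- solve_model(study$model, study$theta_true[study$model$params], design)
  seed <- study$base_seed + as.integer(rep) +
    if (stream == "replicate") 1000000L else 0L
  value <- with_seed(seed,
                     err_sample(study$err, y,
                                study$theta_true[study$err$noise_params]))
  cbind(design, value = value)
}

# Per-replicate profile bounds: psi_hat +/- bound_mult standard errors
# (observed information), clamped to the estimation box.  Keeps a fixed
# fraction of the mesh inside the confidence interval across replicates.
auto_profile_bounds <- function(fit, interest, se, bound_mult = 5) {
  psi <- fit$theta_hat[[interest]]
  s <- se[[interest]]
  lo <- max(fit$lower[[interest]], psi - bound_mult * s)
  hi <- min(fit$upper[[interest]], psi + bound_mult * s)
  c(lo, hi)
}

band_contains <- function(band, values) {
  band$band$lower <= values & values <= band$band$upper
}

#' Run a coverage study
#'
#' Generates `n_reps` synthetic datasets and, for each: fits the MLE,
#' profiles every free parameter, and evaluates containment of the truth
#' (and of a fresh replicate dataset) by every confidence object.  All
#' metrics share the same replicates.  Per replicate the following are
#' recorded:
#' \itemize{
#' \item parameter CIs: truth inside the level `1 - alpha` profile CI, and
#'   the full-likelihood test `l_hat(theta_true) >=` chi-square threshold
#'   with `df` = number of free parameters;
#' \item solution sets (per-parameter, union, full-likelihood grid):
#'   curvewise containment of the whole true trajectory on the truth grid
#'   and per-grid-point containment for each species;
#' \item realization sets (MLE-based, Bonferroni per-parameter/union,
#'   full-likelihood Bonferroni): fraction of the fresh replicate's
#'   observations inside the band at the test times.
#' }
#' Profile meshes use `2 n_profile - 1` points on `psi_hat +/- bound_mult`
#' observed-information standard errors; the full-likelihood grid spans
#' `+/- grid_mult` standard errors with `grid_n` points per axis.
#' Containment is inclusive on both edges.  Replicates whose fit fails are
#' dropped and counted.
#'
#' @param study a [coverage_study()].
#' @param n_reps number of replicates.
#' @param alpha significance level of all sets.
#' @param n_profile profile mesh half-count.
#' @param bound_mult,grid_mult,grid_n mesh/grid extent controls (see above).
#' @param include_full also evaluate the full-likelihood baselines (grid
#'   region per replicate).
#' @param progress print a progress message every `progress` replicates
#'   (0 = silent).
#' @return object of class `pwa_coverage`; see the `summary` element for
#'   headline proportions and Monte-Carlo standard errors.
#' @export
run_coverage_study <- function(study, n_reps, alpha = 0.05, n_profile = 20L,
                               bound_mult = 5, grid_mult = 4, grid_n = 81L,
                               include_full = TRUE, progress = 0L) {
  stopifnot(inherits(study, "pwa_study"), n_reps >= 1L)
  model <- study$model; err <- study$err
  free <- setdiff(full_param_names(model, err), names(study$fixed))
  theta_true_free <- study$theta_true[free]
  truth_design <- obs_design(study$truth_grid, model$species)
  test_design <- obs_design(study$test_times, model$species)
  y_true_grid <- solve_model(model, study$theta_true[model$params],
                             truth_design)
  nu <- length(free)

  par_hit <- matrix(NA, n_reps, nu, dimnames = list(NULL, free))
  full_hit <- rep(NA, n_reps)
  curve_hit <- matrix(NA, n_reps, nu + 2L,
                      dimnames = list(NULL, c(free, "union", "full")))
  point_hit <- array(NA, c(n_reps, nrow(truth_design), nu + 1L),
                     dimnames = list(NULL, NULL, c(free, "union")))
  realiz <- matrix(NA_real_, n_reps, 3L,
                   dimnames = list(NULL, c("mle", "bonf_union", "bonf_full")))
  failed <- 0L

  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      data <- simulate_dataset(study, r)
      fit <- find_mle(data, model, err, study$lower, study$upper,
                      start = theta_true_free, fixed = study$fixed)
      se <- fit_standard_errors(fit)
      if (is.null(se))
        se <- stats::setNames(pmax(0.05 * abs(fit$theta_hat[free]), 0.02), free)

      profs <- list(); cis <- list()
      for (p in free) {
        b <- auto_profile_bounds(fit, p, se, bound_mult)
        profs[[p]] <- profile_parameter(fit, p, b[1L], b[2L], n = n_profile)
        cis[[p]] <- profile_ci(profs[[p]], alpha)
      }

      nll_true <- normalized_log_likelihood(study$theta_true, fit)

      sol_bands <- lapply(profs, solution_set, grid = truth_design,
                          alpha = alpha)
      sol_union <- union_bands(sol_bands)

      region <- NULL
      if (include_full) {
        gs <- stats::setNames(lapply(free, function(p) {
          lo <- max(fit$lower[[p]], fit$theta_hat[[p]] - grid_mult * se[[p]])
          hi <- min(fit$upper[[p]], fit$theta_hat[[p]] + grid_mult * se[[p]])
          seq(lo, hi, length.out = grid_n)
        }), free)
        region <- full_likelihood_region(fit, alpha / 2, grid = gs)
      }

      data_b <- simulate_dataset(study, r, stream = "replicate")
      mle_band <- mle_realization_set(fit, test_design, alpha)
      bonf_union <- union_bands(lapply(profs, bonferroni_realization_set,
                                       grid = test_design, alpha = alpha))
      list(fit = fit, cis = cis, nll_true = nll_true,
           sol_bands = sol_bands, sol_union = sol_union, region = region,
           data_b = data_b, mle_band = mle_band, bonf_union = bonf_union)
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- failed + 1L; next }

    for (p in free)
      par_hit[r, p] <- res$cis[[p]]$lower <= theta_true_free[[p]] &&
                       theta_true_free[[p]] <= res$cis[[p]]$upper
    full_hit[r] <- res$nll_true >= loglik_threshold(alpha, nu)$value

    for (p in free) {
      inside <- band_contains(res$sol_bands[[p]], y_true_grid)
      curve_hit[r, p] <- all(inside)
      point_hit[r, , p] <- inside
    }
    inside_u <- band_contains(res$sol_union, y_true_grid)
    curve_hit[r, "union"] <- all(inside_u)
    point_hit[r, , "union"] <- inside_u

    if (include_full) {
      full_band <- region_solution_set(res$fit, res$region, truth_design,
                                       alpha)
      curve_hit[r, "full"] <- all(band_contains(full_band, y_true_grid))
      full_realiz <- region_realization_set(res$fit, res$region, test_design,
                                            alpha)
      realiz[r, "bonf_full"] <-
        mean(band_contains(full_realiz, res$data_b$value))
    }

    realiz[r, "mle"] <- mean(band_contains(res$mle_band, res$data_b$value))
    realiz[r, "bonf_union"] <-
      mean(band_contains(res$bonf_union, res$data_b$value))

    if (progress > 0L && r %% progress == 0L)
      message("replicate ", r, "/", n_reps)
  }

  n_eff <- n_reps - failed
  prop <- function(x) mean(x, na.rm = TRUE)
  mcse <- function(p) sqrt(p * (1 - p) / n_eff)
  pw <- apply(point_hit, c(2L, 3L), prop)  # grid point x band
  species <- truth_design$species
  summ <- list(
    parameter_ci = vapply(free, function(p) prop(par_hit[, p]), 0),
    full_likelihood_ci = prop(full_hit),
    curvewise = apply(curve_hit, 2L, prop),
    pointwise = pw,
    pointwise_species = species,
    pointwise_times = truth_design$time,
    realization_avg = apply(realiz, 2L, prop),
    n_effective = n_eff, n_failed = failed, alpha = alpha)
  summ$mc_se <- lapply(summ[c("parameter_ci", "curvewise",
                              "realization_avg")],
                       function(v) mcse(v))
  structure(list(study = study, summary = summ,
                 par_hit = par_hit, full_hit = full_hit,
                 curve_hit = curve_hit, point_hit = point_hit,
                 realiz = realiz),
            class = "pwa_coverage")
}

#' @export
print.pwa_coverage <- function(x, ...) {
  s <- x$summary
  cat("<pwa_coverage> ", s$n_effective, " effective replicates (",
      s$n_failed, " failed), alpha = ", s$alpha, "\n", sep = "")
  cat("  parameter CI coverage:",
      paste(names(s$parameter_ci), round(s$parameter_ci, 3), sep = " = ",
            collapse = ", "), "\n")
  cat("  full-likelihood CI coverage:", round(s$full_likelihood_ci, 3), "\n")
  cat("  curvewise solution-set coverage:",
      paste(names(s$curvewise), round(s$curvewise, 3), sep = " = ",
            collapse = ", "), "\n")
  cat("  realization-set average pointwise coverage:",
      paste(names(s$realization_avg), round(s$realization_avg, 3),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Pointwise coverage of a solution band for one species
#'
#' Extracts, from a [run_coverage_study()] result, the per-grid-point
#' coverage proportions of the true trajectory for one band and one
#' species.
#'
#' @param coverage a `pwa_coverage` object.
#' @param band band name: a parameter name or `"union"`.
#' @param species species label.
#' @return data frame with columns `time` and `coverage`.
#' @export
pointwise_coverage <- function(coverage, band, species) {
  stopifnot(inherits(coverage, "pwa_coverage"))
  s <- coverage$summary
  sel <- s$pointwise_species == species
  data.frame(time = s$pointwise_times[sel],
             coverage = s$pointwise[sel, band])
}

#' Coverage of the profile confidence interval for one parameter
#'
#' Convenience wrapper running a coverage study and reporting the fraction
#' of replicates whose profile CI contains the true value.
#'
#' @param study a [coverage_study()].
#' @param interest free parameter name.
#' @param alpha significance level.
#' @param n_reps replicate count.
#' @param ... passed to [run_coverage_study()].
#' @return observed coverage proportion.
#' @export
parameter_ci_coverage <- function(study, interest, alpha = 0.05,
                                  n_reps = 1000L, ...) {
  cov <- run_coverage_study(study, n_reps, alpha, include_full = FALSE, ...)
  cov$summary$parameter_ci[[interest]]
}
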