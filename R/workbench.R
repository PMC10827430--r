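# Case-study fixtures, dataset I/O, and the end-to-end pipeline.

case_study_specs <- function() list(
  fig1_expdecay = list(
    model = function() exp_decay_model(c1_0 = 100),
    err = "gaussian_additive",
    theta_true = c(r1 = 1.0, sigma_N = 5.0),
    design = function(m) obs_design(seq(0, 2, length.out = 21), m$species),
    lower = c(r1 = 0.01, sigma_N = 0.1),
    upper = c(r1 = 5, sigma_N = 50),
    fixed = numeric(0)),
  fig2_linear_gaussian = list(
    model = function() two_pool_model(c1_0 = 100, c2_0 = 25),
    err = "gaussian_additive",
    theta_true = c(r1 = 1.0, r2 = 0.5, sigma_N = 5.0),
    design = function(m) obs_design(seq(0, 2, length.out = 16), m$species),
    lower = c(r1 = 0.01, r2 = 0.01, sigma_N = 0.1),
    upper = c(r1 = 5, r2 = 5, sigma_N = 50),
    fixed = numeric(0)),
  fig3_linear_lognormal_misspec = list(
    model = function() two_pool_model(c1_0 = 100, c2_0 = 10),
    err = "lognormal",                      # data-generating error model
    fit_err = "gaussian_additive",          # deliberately misspecified fit
    theta_true = c(r1 = 1.0, r2 = 0.5, sigma_L = 0.4),
    design = function(m) obs_design(seq(0, 5, length.out = 31), m$species),
    lower = c(r1 = 0.01, r2 = 0.01, sigma_N = 0.1),
    upper = c(r1 = 5, r2 = 5, sigma_N = 100),
    fixed = numeric(0)),
  fig5_linear_lognormal = list(
    model = function() two_pool_model(c1_0 = 100, c2_0 = 10),
    err = "lognormal",
    theta_true = c(r1 = 1.0, r2 = 0.5, sigma_L = 0.4),
    design = function(m) obs_design(seq(0, 5, length.out = 31), m$species),
    lower = c(r1 = 0.01, r2 = 0.01, sigma_L = 0.01),
    upper = c(r1 = 5, r2 = 5, sigma_L = 5),
    fixed = numeric(0)),
  fig6_mm_poisson = list(
    model = function() michaelis_menten_model(c1_0 = 1000, c2_0 = 300),
    err = "poisson",
    theta_true = c(V1 = 100, K1 = 200, V2 = 100, K2 = 200),
    design = function(m) obs_design(seq(0, 25, length.out = 11), m$species),
    lower = c(V1 = 10, K1 = 10, V2 = 10, K2 = 10),
    upper = c(V1 = 500, K1 = 1500, V2 = 500, K2 = 1500),
    fixed = numeric(0)),
  fig7_pde_poisson = list(
    model = function() reaction_diffusion_model(C0 = 100, h = 1),
    err = "poisson",
    theta_true = c(D = 0.5, r1 = 1.2, r2 = 0.8),
    design = function(m) obs_design(c(0.001, 0.25, 0.5, 0.75, 1.0),
                                    m$species,
                                    positions = seq(-2.5, 2.5,
                                                    length.out = 11)),
    lower = c(D = 0.01, r1 = 0.01, r2 = 0.01),
    upper = c(D = 5, r1 = 10, r2 = 10),
    fixed = numeric(0))
)

#' Built-in case studies
#'
#' Constructs a named case study and a synthetic dataset generated from it
#' at the given seed.  Each study records the data-generating model, error
#' model, true parameters, observation design, and estimation bounds; all
#' equally spaced designs include both endpoints.  `fig3_*` deliberately
#' pairs lognormal-generated data with a Gaussian fit (`fit_err`) to study
#' error-model misspecification.  `s4_coverage_study` returns the two-pool
#' Gaussian repeated-sampling study as a [coverage_study()] plus its first
#' replicate dataset.
#'
#' @param name one of `"fig1_expdecay"`, `"fig2_linear_gaussian"`,
#'   `"fig3_linear_lognormal_misspec"`, `"fig5_linear_lognormal"`,
#'   `"fig6_mm_poisson"`, `"fig7_pde_poisson"`, `"s4_coverage_study"`.
#' @param seed integer seed for the dataset draw.
#' @return list with elements `study` (the configuration, or the
#'   `pwa_study` for the coverage study) and `dataset`.
#' @export
make_case_study <- function(name, seed = 1L) {
  if (name == "s4_coverage_study") {
    study <- coverage_study(base_seed = seed)
    return(list(name = name, study = study,
                dataset = simulate_dataset(study, 1L)))
  }
  specs <- case_study_specs()
  if (!name %in% names(specs))
    stop("unknown case study '", name, "'; available: ",
         paste(c(names(specs), "s4_coverage_study"), collapse = ", "))
  sp <- specs[[name]]
  model <- sp$model()
  design <- sp$design(model)
  gen_err <- error_model(sp$err)
  y <- solve_model(model, sp$theta_true[model$params], design)
  value <- with_seed(as.integer(seed),
                     err_sample(gen_err, y,
                                sp$theta_true[gen_err$noise_params]))
  study <- list(name = name, model = model, err = gen_err,
                fit_err = error_model(if (!is.null(sp$fit_err)) sp$fit_err
                                      else sp$err),
                theta_true = sp$theta_true, design = design,
                lower = sp$lower, upper = sp$upper, fixed = sp$fixed,
                seed = as.integer(seed))
  list(name = name, study = study, dataset = cbind(design, value = value))
}

#' Read / write datasets as CSV
#'
#' Datasets are plain CSV with header `time[,position],species,value`.
#' Reading validates the columns and numeric fields and reports the first
#' offending row; writing and re-reading is an identity.
#'
#' @param path file path.
#' @return `read_dataset`: the dataset data frame.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "value")
  if (!all(need %in% names(df)))
    stop("dataset must have columns time,[position,]species,value; missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) > 0L)
    for (col in intersect(c("time", "position", "value"), names(df))) {
      v <- df[[col]]
      if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
        stop("non-numeric or missing '", col, "' at data row ", bad)
      }
    }
  df$species <- as.character(df$species)
  cols <- intersect(c("time", "position", "species", "value"), names(df))
  df[, cols, drop = FALSE]
}

#' @rdname read_dataset
#' @param data dataset to write.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  config
}

#' Run the full estimation-to-prediction pipeline
#'
#' Executes the whole workflow on one dataset: maximum-likelihood fit,
#' univariate profile for every free parameter in turn, profile-wise
#' solution sets and their union, MLE-based and Bonferroni-corrected
#' realization sets and their union, residual diagnostics, and negativity
#' flags.  Any stage failure halts with the stage name.
#'
#' @param config list (or path to a JSON file) with entries:
#'   `model` (registry name), `fixed_constants` (optional, e.g.
#'   `list(c1_0 = 100)`), `error_model`, `data` (a dataset data frame or a
#'   CSV path), `lower`, `upper`, `start` (named), `fixed` (optional named
#'   fixed parameters), `alpha` (default 0.05), `n_mesh` (profile
#'   half-count, default 20), `profile_bounds` (optional named list of
#'   `c(lower, upper)`; defaults to MLE +/- 5 standard errors), and
#'   `grid_n` (prediction grid size, default 100).
#' @param quiet suppress per-stage messages.
#' @return list with `fit`, `profiles`, `cis`, `solution_bands`,
#'   `solution_union`, `mle_realization`, `realization_bands`,
#'   `realization_union`, `residuals`, `qq`, `negativity`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- resolve_config(config)
  say <- function(...) if (!quiet) message(...)
  stage <- function(what, expr) {
    t0 <- proc.time()[3L]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("[%s] done in %.2fs", what, proc.time()[3L] - t0))
    out
  }

  model <- stage("model",
                 model_registry(config[["model"]],
                                as.list(config[["fixed_constants"]] %||%
                                          list())))
  err <- stage("error_model", error_registry(config[["error_model"]]))
  data <- stage("data", {
    if (is.character(config[["data"]])) read_dataset(config[["data"]])
    else as.data.frame(config[["data"]])
  })
  alpha <- config[["alpha"]] %||% 0.05
  n_mesh <- config[["n_mesh"]] %||% 20L
  fixed <- unlist(config[["fixed"]]) %||% numeric(0)

  fit <- stage("fit",
               find_mle(data, model, err,
                        lower = unlist(config[["lower"]]),
                        upper = unlist(config[["upper"]]),
                        start = unlist(config[["start"]]), fixed = fixed,
                        n_starts = config[["n_starts"]] %||% 1L))

  se <- fit_standard_errors(fit)
  profiles <- list(); cis <- list()
  for (p in fit$free_names) {
    profiles[[p]] <- stage(paste0("profile:", p), {
      b <- config[["profile_bounds"]][[p]]
      if (is.null(b)) {
        if (is.null(se)) stop("no usable Hessian; supply profile_bounds")
        b <- auto_profile_bounds(fit, p, se)
      }
      profile_parameter(fit, p, b[1L], b[2L], n = n_mesh)
    })
    cis[[p]] <- profile_ci(profiles[[p]], alpha)
  }

  grid <- prediction_grid(data, model, config[["grid_n"]] %||% 100L)
  solution_bands <- stage("solution_sets",
                          lapply(profiles, solution_set, grid = grid,
                                 alpha = alpha))
  solution_union <- union_bands(solution_bands)
  realization_bands <- stage("realization_sets",
                             lapply(profiles, bonferroni_realization_set,
                                    grid = grid, alpha = alpha))
  realization_union <- union_bands(realization_bands)
  mle_realization <- mle_realization_set(fit, grid, alpha)

  diagnostics <- stage("diagnostics", {
    fitted <- solve_model(model, fit$theta_hat[model$params],
                          data[, setdiff(names(data), "value"),
                               drop = FALSE])
    kind <- if (err$name == "lognormal") "ratio" else "additive"
    res <- residual_set(data, fitted, kind)
    list(residuals = res,
         qq = qq_points(res, if (kind == "ratio") "lognormal" else "normal"))
  })

  list(fit = fit, profiles = profiles, cis = cis,
       solution_bands = solution_bands, solution_union = solution_union,
       mle_realization = mle_realization,
       realization_bands = realization_bands,
       realization_union = realization_union,
       residuals = diagnostics$residuals, qq = diagnostics$qq,
       negativity = negativity_flag(realization_union))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a band to a data frame / CSV
#'
#' Long-format export with one row per grid point: grid columns, `lower`,
#' `upper`, plus `source`, `kind` and `level` columns — everything needed
#' to replot a figure.
#'
#' @param band a `pwa_band`.
#' @param path optional CSV path; when given the frame is also written.
#' @return the data frame, invisibly when `path` is given.
#' @export
band_to_frame <- function(band, path = NULL) {
  df <- band$band
  df$source <- band$source
  df$kind <- band$kind
  df$level <- band$level
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Serialise a fit to JSON
#'
#' @param fit a [find_mle()] result.
#' @param path optional JSON path.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(model = fit$model$name, error_model = fit$err$name,
              theta = as.list(fit$theta_hat),
              fixed = as.list(fit$fixed),
              lower = as.list(fit$lower), upper = as.list(fit$upper),
              loglik = fit$loglik_hat, converged = fit$converged,
              n_evals = fit$n_evals)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
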