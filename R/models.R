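#' Observation design
#'
#' Builds the design at which a mechanistic model is evaluated: every
#' combination of the supplied times (and, for spatio-temporal models,
#' positions) with every species.  The result is a plain data frame with
#' columns `time`, optionally `position`, and `species`; model solvers and
#' datasets share this layout, one row per scheduled observation.
#'
#' @param times numeric vector of observation times (finite, >= 0).
#' @param species character vector of species labels, e.g. `c("c1", "c2")`.
#' @param positions optional numeric vector of spatial positions; when given,
#'   the design is the full `times x positions x species` grid.
#' @return data frame with one row per (time\[, position\], species) record.
#' @examples
#' obs_design(seq(0, 2, length.out = 16), c("c1", "c2"))
#' @export
obs_design <- function(times, species = "c1", positions = NULL) {
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
            is.character(species), length(species) >= 1)
  if (is.null(positions)) {
    d <- expand.grid(time = times, species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.numeric(positions), all(is.finite(positions)))
    d <- expand.grid(time = times, position = positions, species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- d[order(d$species, d$time, d$position), , drop = FALSE]
    rownames(d) <- NULL
    return(d)
  }
  d <- d[order(d$species, d$time), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Construct a mechanistic model
#'
#' A `pwa_model` couples a deterministic solver with the bookkeeping the
#' inference machinery needs: ordered parameter names, species labels, and
#' fixed constants (initial conditions and geometry are treated as known
#' throughout).  `solve_fn(theta, design)` must be deterministic and return
#' one finite value per design row for parameters within bounds.  An optional
#' `solve_grid_fn(theta_mat, design)` evaluates many parameter vectors at
#' once (rows of `theta_mat`) and returns an `nrow(theta_mat) x nrow(design)`
#' matrix; it is used to accelerate grid regions and band envelopes and must
#' agree with `solve_fn` row by row.
#'
#' @param name model identifier.
#' @param params ordered character vector of mechanistic parameter names.
#' @param species character vector of observable species labels.
#' @param fixed named numeric vector of known constants.
#' @param solve_fn function `(theta, design) -> numeric`.
#' @param solve_grid_fn optional vectorised solver (see above).
#' @param spatial logical; `TRUE` when the design needs a `position` column.
#' @return object of class `pwa_model`.
#' @seealso [exp_decay_model()], [two_pool_model()],
#'   [michaelis_menten_model()], [reaction_diffusion_model()]
#' @export
pwa_model <- function(name, params, species, fixed, solve_fn,
                      solve_grid_fn = NULL, spatial = FALSE) {
  stopifnot(is.character(name), is.character(params), is.character(species),
            is.function(solve_fn))
  structure(list(name = name, params = params, species = species,
                 fixed = fixed, solve_fn = solve_fn,
                 solve_grid_fn = solve_grid_fn, spatial = spatial),
            class = "pwa_model")
}

#' @export
print.pwa_model <- function(x, ...) {
  cat("<pwa_model> ", x$name, "\n", sep = "")
  cat("  parameters:", paste(x$params, collapse = ", "), "\n")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:     ", paste(names(x$fixed), signif(unlist(x$fixed), 6),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a mechanistic model on a design
#'
#' @param model a [pwa_model()].
#' @param theta named numeric vector of the model's mechanistic parameters.
#' @param design observation design from [obs_design()] (or the design
#'   columns of a dataset).
#' @return numeric vector of noise-free solution values, one per design row.
#' @export
solve_model <- function(model, theta, design) {
  stopifnot(inherits(model, "pwa_model"))
  theta <- theta[model$params]
  if (anyNA(theta))
    stop("missing mechanistic parameters: ",
         paste(setdiff(model$params, names(theta)), collapse = ", "))
  if (any(!is.finite(theta))) stop("non-finite mechanistic parameters")
  if (model$spatial && is.null(design$position))
    stop("spatio-temporal model requires a 'position' column in the design")
  y <- model$solve_fn(theta, design)
  stopifnot(length(y) == nrow(design))
  y
}

# Evaluate many parameter vectors at once; falls back to a row loop when the
# model supplies no vectorised solver.
solve_model_grid <- function(model, theta_mat, design) {
  theta_mat <- theta_mat[, model$params, drop = FALSE]
  if (!is.null(model$solve_grid_fn)) return(model$solve_grid_fn(theta_mat, design))
  t(apply(theta_mat, 1L, function(th) model$solve_fn(th, design)))
}

# Numerical integration helper: solves dy/dt = deriv(t, y) from t = 0 and
# returns the solution at the requested (possibly unsorted, duplicated)
# times.  Tight tolerances keep likelihood surfaces smooth for optimisation.
ode_at_times <- function(times, init, deriv, rtol = 1e-9, atol = 1e-9) {
  grid <- sort(unique(c(0, times)))
  out <- deSolve::ode(y = init, times = grid,
                      func = function(t, y, p) list(deriv(t, y)),
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE solver failed (istate ", attr(out, "istate")[1L], ")")
  sol <- out[, -1L, drop = FALSE]
  sol[match(times, grid), , drop = FALSE]
}

#' Exponential decay model
#'
#' One species `c1` decaying at rate `r1`: `c1(t) = c1(0) exp(-r1 t)`.
#' The initial concentration is a fixed known constant.
#'
#' @param c1_0 known initial concentration (>= 0).
#' @return a [pwa_model()] with parameter `r1`.
#' @examples
#' m <- exp_decay_model(100)
#' solve_model(m, c(r1 = 1), obs_design(c(0, 1)))
#' @export
exp_decay_model <- function(c1_0 = 100) {
  stopifnot(c1_0 >= 0)
  solve_fn <- function(theta, design) {
    r1 <- theta[["r1"]]
    if (r1 < 0) stop("r1 must be non-negative")
    c1_0 * exp(-r1 * design$time)
  }
  grid_fn <- function(theta_mat, design) {
    c1_0 * exp(-outer(theta_mat[, "r1"], design$time))
  }
  pwa_model("exp_decay", "r1", "c1", c(c1_0 = c1_0), solve_fn, grid_fn)
}

# Relative tolerance below which the two-pool closed form is abandoned for
# numerical integration (removable singularity at r1 = r2).
.two_pool_tol <- 1e-6

two_pool_closed_form <- function(r1, r2, c1_0, c2_0, times, species) {
  a <- r1 / (r2 - r1)
  c1 <- c1_0 * exp(-r1 * times)
  ifelse(species == "c1", c1, a * c1 + (c2_0 - c1_0 * a) * exp(-r2 * times))
}

two_pool_rhs <- function(r1, r2) {
  function(t, y) c(-r1 * y[1L], r1 * y[1L] - r2 * y[2L])
}

#' Two-pool linear reaction model
#'
#' Chemical `C1` decays into `C2` at rate `r1`; `C2` decays at rate `r2`
#' (mass-action kinetics, decay products of the second reaction not tracked):
#' `dc1/dt = -r1 c1`, `dc2/dt = r1 c1 - r2 c2`.  The closed-form solution is
#' used when `|r1 - r2|` is large enough relative to the rates; near the
#' removable singularity `r1 = r2` the system is integrated numerically,
#' which needs no case split.
#'
#' @param c1_0,c2_0 known initial concentrations.
#' @return a [pwa_model()] with parameters `r1`, `r2` and species
#'   `c1`, `c2`.
#' @examples
#' m <- two_pool_model(100, 25)
#' d <- obs_design(seq(0, 2, length.out = 16), c("c1", "c2"))
#' head(solve_model(m, c(r1 = 1, r2 = 0.5), d))
#' @export
two_pool_model <- function(c1_0 = 100, c2_0 = 25) {
  stopifnot(c1_0 >= 0, c2_0 >= 0)
  degenerate <- function(r1, r2) abs(r1 - r2) < .two_pool_tol * max(r1, r2, 1)
  solve_fn <- function(theta, design) {
    r1 <- theta[["r1"]]; r2 <- theta[["r2"]]
    if (!is.finite(r1) || !is.finite(r2)) stop("non-finite rates")
    if (r1 < 0 || r2 < 0) stop("rates must be non-negative")
    if (degenerate(r1, r2)) {
      sol <- ode_at_times(design$time, c(c1_0, c2_0), two_pool_rhs(r1, r2))
      ifelse(design$species == "c1", sol[, 1L], sol[, 2L])
    } else {
      two_pool_closed_form(r1, r2, c1_0, c2_0, design$time, design$species)
    }
  }
  grid_fn <- function(theta_mat, design) {
    r1 <- theta_mat[, "r1"]; r2 <- theta_mat[, "r2"]
    a <- r1 / (r2 - r1)
    e1 <- exp(-outer(r1, design$time))
    e2 <- exp(-outer(r2, design$time))
    out <- c1_0 * a * e1 + (c2_0 - c1_0 * a) * e2   # c2 columns (row-wise a)
    is_c1 <- design$species == "c1"
    out[, is_c1] <- c1_0 * e1[, is_c1]
    bad <- which(abs(r1 - r2) < .two_pool_tol * pmax(r1, r2, 1))
    for (i in bad)
      out[i, ] <- solve_fn(c(r1 = r1[i], r2 = r2[i]), design)
    out
  }
  pwa_model("two_pool_linear", c("r1", "r2"), c("c1", "c2"),
            c(c1_0 = c1_0, c2_0 = c2_0), solve_fn, grid_fn)
}

#' Michaelis--Menten two-pool model
#'
#' Rate-limited nonlinear variant of the two-pool system:
#' `dc1/dt = -V1 c1 / (K1 + c1)`,
#' `dc2/dt =  V1 c1 / (K1 + c1) - V2 c2 / (K2 + c2)`,
#' with maximum rates `V1`, `V2` and Michaelis constants `K1`, `K2`.
#' Solved numerically with an adaptive integrator at tolerances tight enough
#' (default 1e-9) that halving them leaves outputs unchanged to well below
#' 1e-6 relative.
#'
#' @param c1_0,c2_0 known initial concentrations.
#' @param rtol,atol solver tolerances.
#' @return a [pwa_model()] with parameters `V1`, `K1`, `V2`, `K2`.
#' @export
michaelis_menten_model <- function(c1_0 = 1000, c2_0 = 300,
                                   rtol = 1e-9, atol = 1e-9) {
  solve_fn <- function(theta, design) {
    V1 <- theta[["V1"]]; K1 <- theta[["K1"]]
    V2 <- theta[["V2"]]; K2 <- theta[["K2"]]
    if (V1 < 0 || V2 < 0) stop("maximum rates must be non-negative")
    if (K1 <= 0 || K2 <= 0) stop("Michaelis constants must be positive")
    rhs <- function(t, y) {
      f1 <- V1 * y[1L] / (K1 + y[1L])
      c(-f1, f1 - V2 * y[2L] / (K2 + y[2L]))
    }
    sol <- tryCatch(ode_at_times(design$time, c(c1_0, c2_0), rhs, rtol, atol),
                    error = function(e) stop("solver failure at theta = (",
                      paste(signif(theta, 6), collapse = ", "), "): ",
                      conditionMessage(e)))
    ifelse(design$species == "c1", sol[, 1L], sol[, 2L])
  }
  pwa_model("michaelis_menten", c("V1", "K1", "V2", "K2"), c("c1", "c2"),
            c(c1_0 = c1_0, c2_0 = c2_0), solve_fn)
}

erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Reaction--diffusion model with confined release
#'
#' Two chemical species diffusing on the infinite line with the linear
#' two-pool reactions: `C1` is released at concentration `C0` from the
#' confined region `|x| < h` at `t = 0` (`C2` starts at zero everywhere),
#' both species diffuse with constant diffusivity `D`, `C1` converts to `C2`
#' at rate `r1` and `C2` decays at rate `r2`.  For `r1 != r2` the solution
#' has the closed form
#' `c1(t,x) = (C0/2) [erf((h-x)/(2 sqrt(D t))) + erf((h+x)/(2 sqrt(D t)))] exp(-r1 t)`
#' and `c2(t,x) = (r1/(r2-r1)) (C0/2) [..same..] (exp(-r1 t) - exp(-r2 t))`.
#' At `r1 = r2` (removable singularity, closed form not tabulated here) the
#' model evaluates at `r2` perturbed by +/-1e-8 and averages.  The initial
#' condition is discontinuous, so `t = 0` is rejected; callers wanting the
#' earliest plotted state pass a small positive time such as 1e-3 explicitly.
#'
#' @param C0 known release concentration.
#' @param h known half-width of the release region.
#' @return a spatio-temporal [pwa_model()] with parameters `D`, `r1`, `r2`.
#' @export
reaction_diffusion_model <- function(C0 = 100, h = 1) {
  stopifnot(C0 >= 0, h > 0)
  core <- function(D, r1, r2, t, x, species) {
    s <- 2 * sqrt(D * t)
    pulse <- (C0 / 2) * (erf((h - x) / s) + erf((h + x) / s))
    ifelse(species == "c1",
           pulse * exp(-r1 * t),
           (r1 / (r2 - r1)) * pulse * (exp(-r1 * t) - exp(-r2 * t)))
  }
  solve_fn <- function(theta, design) {
    D <- theta[["D"]]; r1 <- theta[["r1"]]; r2 <- theta[["r2"]]
    if (D <= 0) stop("diffusivity D must be positive")
    if (r1 < 0 || r2 < 0) stop("rates must be non-negative")
    if (any(design$time <= 0))
      stop("t <= 0 not admitted: the initial condition is discontinuous")
    if (abs(r1 - r2) < 1e-7 * max(r1, r2, 1)) {
      eps <- 1e-8
      (core(D, r1, r2 + eps, design$time, design$position, design$species) +
       core(D, r1, r2 - eps, design$time, design$position, design$species)) / 2
    } else {
      core(D, r1, r2, design$time, design$position, design$species)
    }
  }
  pwa_model("reaction_diffusion", c("D", "r1", "r2"), c("c1", "c2"),
            c(C0 = C0, h = h), solve_fn, spatial = TRUE)
}

# Registry used by JSON configs and the command line.
model_registry <- function(name, fixed = list()) {
  fx <- function(key, default) if (!is.null(fixed[[key]])) fixed[[key]] else default
  switch(name,
    exp_decay = exp_decay_model(fx("c1_0", 100)),
    two_pool_linear = two_pool_model(fx("c1_0", 100), fx("c2_0", 25)),
    michaelis_menten = michaelis_menten_model(fx("c1_0", 1000), fx("c2_0", 300)),
    reaction_diffusion = reaction_diffusion_model(fx("C0", 100), fx("h", 1)),
    stop("unknown model '", name, "'"))
}
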