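#' Chi-square log-likelihood threshold
#'
#' Threshold on the normalized log-likelihood calibrating likelihood-based
#' confidence sets: `l_c = -Delta_{nu,1-alpha} / 2` where `Delta_{nu,1-alpha}`
#' is the `1 - alpha` quantile of the chi-square distribution with `nu`
#' degrees of freedom (the dimension of the interest parameter, `nu = 1` for
#' univariate profiles).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom `nu >= 1`.
#' @return object of class `pwa_threshold` with fields `alpha`, `df`,
#'   `value` (always negative for `alpha < 1`).
#' @examples
#' loglik_threshold(0.05, 1)$value  # -1.92073
#' loglik_threshold(0.05, 2)$value  # -2.99573
#' @export
loglik_threshold <- function(alpha, df) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  structure(list(alpha = alpha, df = df,
                 value = -stats::qchisq(1 - alpha, df) / 2),
            class = "pwa_threshold")
}

# Maximises the log-likelihood over the nuisance parameters at fixed psi.
# 0 nuisance: direct evaluation.  1 nuisance: Brent.  >1: Nelder-Mead on the
# logit box, warm-started from the neighbouring mesh point.
optimise_nuisance <- function(objective, lam_start, lam_lower, lam_upper) {
  k <- length(lam_start)
  if (k == 0L)
    return(list(value = objective(numeric(0)), lambda = numeric(0)))
  if (k == 1L) {
    res <- stats::optimize(function(x) objective(x),
                           lower = lam_lower, upper = lam_upper,
                           maximum = TRUE, tol = 1e-6)
    return(list(value = res$objective, lambda = res$maximum))
  }
  neg <- function(v) -objective(u_to_box(v, lam_lower, lam_upper))
  res <- stats::optim(box_to_u(lam_start, lam_lower, lam_upper), neg,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-9))
  list(value = -res$value, lambda = u_to_box(res$par, lam_lower, lam_upper))
}

#' Univariate profile log-likelihood
#'
#' For a scalar interest parameter `psi`, the profile log-likelihood is the
#' supremum of the normalized log-likelihood over the nuisance parameters at
#' each fixed `psi`.  It is evaluated on a mesh of `n` equally spaced points
#' from `lower` to the MLE `psi_hat` and `n` from `psi_hat` to `upper`
#' (`psi_hat` is a mesh point, so 2n - 1 distinct values), sweeping outward
#' from the MLE so that each nuisance optimisation is warm-started from its
#' neighbour's optimum.  A peaked profile relative to the chi-square
#' threshold signals a practically identifiable parameter; a wide flat one
#' signals practical non-identifiability.
#'
#' @param fit a [find_mle()] result.
#' @param interest name of the free parameter to profile.
#' @param lower,upper pre-specified profiling bounds with
#'   `lower < psi_hat < upper`; choose them wide enough to capture the
#'   confidence intervals of interest.
#' @param n mesh half-count (>= 2; default 20).
#' @return object of class `pwa_profile`: `mesh`, `values` (normalized
#'   profile log-likelihoods, max 0 at `psi_hat`), `nuisance` (matrix of
#'   optimal nuisance values per mesh point), `psi_hat`, and the `fit`.
#'   If a better optimum than the stored MLE is found during profiling the
#'   curve is renormalized to it and `renormalized` is set.
#' @export
profile_parameter <- function(fit, interest, lower, upper, n = 20L) {
  stopifnot(inherits(fit, "pwa_fit"), n >= 2L)
  free <- fit$free_names
  if (!interest %in% free)
    stop("'", interest, "' is not a free parameter of the fit")
  psi_hat <- fit$theta_hat[[interest]]
  if (!(lower < psi_hat && psi_hat < upper))
    stop("need lower < psi_hat (", signif(psi_hat, 6), ") < upper")
  nuis <- setdiff(free, interest)
  idx_psi <- match(interest, free)
  idx_nui <- match(nuis, free)
  ll <- fit$loglik_fn
  lam_hat <- fit$theta_hat[nuis]

  mesh <- sort(unique(c(seq(lower, psi_hat, length.out = n),
                        seq(psi_hat, upper, length.out = n))))
  m <- length(mesh)
  i_hat <- which.min(abs(mesh - psi_hat))
  values <- rep(NA_real_, m)
  lambda <- matrix(NA_real_, m, length(nuis), dimnames = list(NULL, nuis))

  eval_at <- function(psi, lam_start) {
    obj <- function(lam) {
      x <- numeric(length(free))
      x[idx_psi] <- psi
      x[idx_nui] <- lam
      ll(x)
    }
    optimise_nuisance(obj, lam_start, fit$lower[nuis], fit$upper[nuis])
  }

  values[i_hat] <- fit$loglik_hat
  lambda[i_hat, ] <- lam_hat
  failed <- logical(m)
  for (dir in c(-1L, 1L)) {
    lam_prev <- lam_hat
    i <- i_hat + dir
    while (i >= 1L && i <= m) {
      res <- tryCatch(eval_at(mesh[i], lam_prev), error = function(e) NULL)
      if (is.null(res)) {
        failed[i] <- TRUE
      } else {
        values[i] <- res$value
        lambda[i, ] <- res$lambda
        lam_prev <- res$lambda
      }
      i <- i + dir
    }
  }
  if (any(failed))
    warning(sum(failed), " mesh point(s) failed nuisance optimisation; ",
            "recorded as missing")

  top <- max(values, na.rm = TRUE)
  renorm <- top > fit$loglik_hat + 1e-6
  values <- values - max(top, fit$loglik_hat)

  structure(list(interest = interest, mesh = mesh, values = values,
                 nuisance = lambda, psi_hat = psi_hat, i_hat = i_hat,
                 failed = failed, renormalized = renorm,
                 bounds = c(lower = lower, upper = upper), fit = fit),
            class = "pwa_profile")
}

#' @export
print.pwa_profile <- function(x, ...) {
  cat("<pwa_profile> ", x$interest, ": ", length(x$mesh),
      " mesh points on [", signif(x$bounds[1L], 6), ", ",
      signif(x$bounds[2L], 6), "], psi_hat = ", signif(x$psi_hat, 6),
      "\n", sep = "")
  ci <- tryCatch(profile_ci(x), error = function(e) NULL)
  if (!is.null(ci))
    cat("  95% CI: (", signif(ci$lower, 6), ", ", signif(ci$upper, 6), ")",
        if (any(ci$truncated)) "  [truncated]", "\n", sep = "")
  invisible(x)
}

#' Confidence interval from a profile log-likelihood
#'
#' The likelihood-based approximate confidence interval is the set of `psi`
#' with profile value at or above the chi-square threshold
#' ([loglik_threshold()] with `df = 1`).  Endpoints are located by linear
#' interpolation between the adjacent mesh points bracketing the threshold.
#' A side on which the profile never drops below the threshold is truncated
#' at the profiling bound and flagged — the signature of practical
#' non-identifiability.  If the super-threshold set is not contiguous
#' (multimodal profile), the outermost crossings are reported and
#' `multimodal` is set with a warning.
#'
#' @param profile a [profile_parameter()] result with >= 3 valid mesh
#'   points.
#' @param alpha significance level (default 0.05).
#' @return list with `lower`, `upper`, `truncated` (logical pair),
#'   `multimodal`, `alpha`, and the threshold used.
#' @export
profile_ci <- function(profile, alpha = 0.05) {
  stopifnot(inherits(profile, "pwa_profile"))
  ok <- !is.na(profile$values)
  if (sum(ok) < 3L) stop("fewer than 3 valid mesh points")
  mesh <- profile$mesh[ok]
  v <- profile$values[ok]
  lc <- loglik_threshold(alpha, 1L)$value
  above <- v >= lc
  if (!any(above))
    stop("no mesh point reaches the threshold; profile inconsistent with MLE")
  idx <- which(above)
  multimodal <- any(diff(idx) > 1L)
  if (multimodal)
    warning("profile super-threshold set is not contiguous; ",
            "reporting outermost crossings")
  lo_i <- idx[1L]; hi_i <- idx[length(idx)]
  interp <- function(i0, i1) {
    # linear interpolation of the crossing between mesh points i0 (below)
    # and i1 (above)
    mesh[i0] + (lc - v[i0]) * (mesh[i1] - mesh[i0]) / (v[i1] - v[i0])
  }
  trunc_lo <- lo_i == 1L
  trunc_hi <- hi_i == length(mesh)
  lower <- if (trunc_lo) mesh[1L] else interp(lo_i - 1L, lo_i)
  upper <- if (trunc_hi) mesh[length(mesh)] else interp(hi_i + 1L, hi_i)
  list(lower = lower, upper = upper,
       truncated = c(lower = trunc_lo, upper = trunc_hi),
       multimodal = multimodal, alpha = alpha,
       threshold = lc)
}
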