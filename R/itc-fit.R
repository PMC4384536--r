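#' Fit the one-set-of-sites model to a thermogram
#'
#' Non-linear least squares fit of normalized injection heats to the
#' one-set-of-sites isotherm, by Levenberg-Marquardt on
#' \eqn{(\log K_a, \Delta H, n)}. The log parameterisation keeps the
#' association constant positive. Standard errors come from the curvature of
#' the fit; derived thermodynamic quantities (Kd, \eqn{\Delta G},
#' \eqn{T\Delta S}) are computed with [binding_thermodynamics()].
#'
#' A warning (never an error) is raised when the Wiseman `c` value
#' \eqn{c = n K_a M_0} falls outside roughly 1-1000, where the affinity is
#' poorly determined by a single titration.
#'
#' @param observed A thermogram data frame with columns `injection` and
#'   `ndh_kcal_per_mol` (heat per mole of injectant), as produced by
#'   [simulate_thermogram()] or read from disk. At least 6 injections after
#'   any discard.
#' @param experiment The [itc_experiment()] describing the titration geometry.
#' @param start Optional named list/vector with starting values `kd`,
#'   `enthalpy`, `n`. Defaults: `n = 1`, `enthalpy` = first retained
#'   normalized heat, `kd` chosen so that `c = 10`.
#' @param drop_first Discard the first injection before fitting (default
#'   `TRUE`, the usual treatment of the small pre-injection).
#' @param fix_n Optional fixed stoichiometry; when given, only
#'   \eqn{(\log K_a, \Delta H)} are free.
#' @return An object of class `itc_fit`; see [tidy.itc_fit()] and
#'   [glance.itc_fit()]. The element `parameters` is a
#'   [binding_parameters()] row with the point estimates.
#' @examples
#' exp <- itc_experiment(cell_conc = 14e-6, syringe_conc = 210e-6)
#' tg <- simulate_thermogram(exp, binding_parameters(kd = 457e-9, enthalpy = -10))
#' fit <- fit_one_site(tg, exp)
#' tidy(fit)
#' @export
fit_one_site <- function(observed, experiment, start = NULL,
                         drop_first = TRUE, fix_n = NULL) {
  stopifnot(inherits(experiment, "itc_experiment"))
  if (!is.data.frame(observed) || !"ndh_kcal_per_mol" %in% names(observed)) {
    abort("`observed` must be a data frame with an `ndh_kcal_per_mol` column.",
          class = "clampeq_schema")
  }
  conc <- titration_concentrations(experiment)
  if (nrow(observed) != nrow(conc)) {
    abort(sprintf("Thermogram has %d injections but the experiment defines %d.",
                  nrow(observed), nrow(conc)), class = "clampeq_schema")
  }
  keep <- if (drop_first) -1L else seq_len(nrow(conc))
  y <- observed$ndh_kcal_per_mol[keep]
  if (length(y) < 6L || anyNA(y) || any(!is.finite(y))) {
    abort("Need at least 6 finite retained injections to fit.",
          class = "clampeq_invalid_parameter")
  }

  dv <- experiment$injection_volumes
  v0 <- experiment$cell_volume
  predict_ndh <- function(ka, dh, n) {
    q <- one_site_cumulative_heat(1 / ka, dh, n, conc$macromolecule,
                                  conc$titrant, v0)
    q_prev <- c(0, q[-length(q)])
    dq <- q + (dv / v0) * (q + q_prev) / 2 - q_prev
    ndh_from_heats(dq, dv, experiment$syringe_conc)[keep]
  }

  m0 <- experiment$cell_conc
  dh0 <- if (!is.null(start$enthalpy)) start$enthalpy else y[1]
  if (!is.finite(dh0) || dh0 == 0) dh0 <- if (all(y == 0)) -1 else stats::median(y[y != 0])
  n0 <- if (!is.null(start$n)) start$n else 1
  ka0 <- if (!is.null(start$kd)) 1 / start$kd else 10 / (n0 * m0)

  free_n <- is.null(fix_n)
  par0 <- if (free_n) c(log_ka = log(ka0), enthalpy = dh0, n = n0)
          else c(log_ka = log(ka0), enthalpy = dh0)
  resid_fn <- function(p) {
    n <- if (free_n) p[["n"]] else fix_n
    if (n <= 0) return(rep(1e6, length(y)))
    predict_ndh(exp(p[["log_ka"]]), p[["enthalpy"]], n) - y
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))

  p <- fit$par
  ka <- exp(p[["log_ka"]])
  n_hat <- if (free_n) p[["n"]] else fix_n
  dh_hat <- p[["enthalpy"]]

  se <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], rownames(co))
  }, error = function(e) stats::setNames(rep(NA_real_, length(par0)), names(par0)))

  c_value <- n_hat * ka * m0
  c_warning <- !is.finite(c_value) || c_value < 1 || c_value > 1000
  if (c_warning) {
    warn(sprintf("Wiseman c value %.3g is outside ~1-1000; the affinity is poorly determined by this titration.",
                 c_value), class = "clampeq_c_value")
  }
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(sprintf("Levenberg-Marquardt did not report convergence (info = %d: %s).",
                 fit$info, fit$message), class = "clampeq_numerical")
  }

  dof <- length(y) - length(par0)
  sigma <- sqrt(fit$deviance / max(dof, 1))
  fitted_ndh <- predict_ndh(ka, dh_hat, n_hat)

  structure(list(
    parameters = binding_parameters(kd = 1 / ka, enthalpy = dh_hat, n = n_hat,
                                    temperature = experiment$temperature),
    std_errors = c(
      log_ka = unname(se["log_ka"]),
      enthalpy = unname(se["enthalpy"]),
      n = if (free_n) unname(se["n"]) else NA_real_
    ),
    experiment = experiment,
    data = tibble(injection = conc$injection[keep],
                  molar_ratio = conc$molar_ratio[keep],
                  observed = y, fitted = fitted_ndh),
    c_value = c_value, c_warning = c_warning,
    converged = converged, info = fit$info, message = fit$message,
    deviance = fit$deviance, sigma = sigma, df.residual = dof,
    niter = fit$niter
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<itc_fit> one-set-of-sites: Kd = %.4g M, dH = %.4g kcal/mol, n = %.3f (c = %.3g%s)\n",
              p$kd, p$enthalpy, p$n, x$c_value,
              if (x$c_warning) ", flagged" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ITC fit
#'
#' One row per fitted or derived quantity. Standard errors for `kd` are
#' delta-method transforms of the `log Ka` error; derived energies carry no
#' propagated error.
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `unit`.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  p <- x$parameters
  th <- binding_thermodynamics(p$kd, p$enthalpy, p$temperature_K)
  se <- x$std_errors
  tibble(
    term = c("n", "enthalpy", "ka", "kd", "delta_G", "T_delta_S"),
    estimate = c(p$n, p$enthalpy, p$ka, p$kd, th$delta_G, th$T_delta_S),
    std.error = c(se[["n"]], se[["enthalpy"]],
                  p$ka * se[["log_ka"]], p$kd * se[["log_ka"]],
                  NA_real_, NA_real_),
    unit = c("sites", "kcal/mol", "1/M", "M", "kcal/mol", "kcal/mol")
  )
}

#' Glance at an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries including the Wiseman
#'   `c` value and its out-of-range flag.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(sigma = x$sigma, deviance = x$deviance, df.residual = x$df.residual,
         nobs = nrow(x$data), c_value = x$c_value, c_warning = x$c_warning,
         converged = x$converged, niter = x$niter)
}
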