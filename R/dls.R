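#' Probability that an accessory-helix cross-link is engaged
#'
#' For a complex that self-associates through a single interface with
#' dissociation constant `kd`, the bound fraction at initial concentration
#' C follows from the quadratic equilibrium
#' \eqn{[\mathrm{unbound}]^2 = K_d [\mathrm{bound}]}:
#' \deqn{p = 1 - \frac{K_d\left(\sqrt{1+4C/K_d}-1\right)}{2C}.}
#' `p = 0` at C = 0 (defined limit) and `p -> 1` as C grows.
#'
#' @param c_initial Initial complex concentration(s), molar (>= 0).
#' @param kd Cross-link dissociation constant, molar.
#' @return Bound probability in `[0, 1)`, same length as `c_initial`.
#' @export
bound_probability <- function(c_initial, kd) {
  check_positive(c_initial, "c_initial", strict = FALSE)
  check_positive(kd, "kd")
  # 1 - unbound/C in cancellation-free form; exact 0 at C = 0
  1 - 2 / (sqrt(1 + 4 * c_initial / kd) + 1)
}

#' Mean oligomer size from the cross-link occupancy
#'
#' A chain grows by one monomer per engaged interface, so with bound
#' probability `p` the average chain length is
#' \eqn{N = p/(1-p) + 1 = 1/(1-p)}.
#'
#' @param p Bound probability, in `[0, 1)`.
#' @return Mean number of monomers per particle, >= 1.
#' @export
mean_oligomer_size <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p >= 1)) {
    abort("`p` must lie in [0, 1).", class = "clampeq_invalid_parameter")
  }
  1 / (1 - p)
}

#' Gyration radius of an N-mer
#'
#' Ideal-chain scaling of particle size with the mean oligomer number:
#' \eqn{r = \sqrt{N}\, r_0}, where `r0` is the monomer spacing within the
#' array. Quantitative for long ideal polymers, semi-quantitative for the
#' small oligomers modelled here.
#'
#' @param n_mer Mean oligomer size, >= 1.
#' @param r0 Monomer spacing, nm.
#' @return Radius in nm; equals `r0` at `n_mer = 1`.
#' @export
gyration_radius <- function(n_mer, r0) {
  if (!is.numeric(n_mer) || anyNA(n_mer) || any(n_mer < 1)) {
    abort("`n_mer` must be >= 1.", class = "clampeq_invalid_parameter")
  }
  check_positive(r0, "r0")
  sqrt(n_mer) * r0
}

#' Predicted radius-versus-concentration curve
#'
#' Composes occupancy, mean oligomer size and the gyration-radius scaling
#' into the observable a light-scattering titration measures. The closed
#' form is \eqn{r(C) = r_0\sqrt{(1+\sqrt{1+4C/K_d})/2}}: monotone increasing
#' in C, decreasing in Kd, linear in r0.
#'
#' @param kd Cross-link dissociation constant, molar.
#' @param r0 Monomer spacing, nm.
#' @param concentrations Initial complex concentrations, molar, ascending.
#' @return A tibble of class `dls_curve` with columns `concentration` (M),
#'   `p`, `n_mer`, `radius_nm`.
#' @examples
#' predict_radius_curve(25e-6, 3.5, c(5, 10, 25, 50, 100) * 1e-6)
#' @export
predict_radius_curve <- function(kd, r0, concentrations) {
  check_positive(concentrations, "concentrations", strict = FALSE)
  if (is.unsorted(concentrations, strictly = FALSE)) {
    abort("`concentrations` must be sorted ascending.",
          class = "clampeq_invalid_parameter")
  }
  p <- bound_probability(concentrations, kd)
  n <- mean_oligomer_size(p)
  out <- tibble(concentration = concentrations, p = p, n_mer = n,
                radius_nm = gyration_radius(n, r0))
  class(out) <- c("dls_curve", class(out))
  out
}

#' Fit the oligomerization model to a radius-concentration series
#'
#' Weighted least squares of measured radii against
#' \eqn{r(C) = r_0\sqrt{(1+\sqrt{1+4C/K_d})/2}} over
#' \eqn{(\log K_d, r_0)}, by Levenberg-Marquardt. When `radius_sd_nm` is
#' present, residuals are inverse-variance weighted. `r0` is constrained to
#' (0.5, 20) nm and `Kd` to at most `kd_max`.
#'
#' The fit is flagged as a non-specific / low-affinity aggregation regime
#' when the fitted Kd lands at the `kd_max` bound or exceeds the largest
#' sampled concentration — in either case the data never reach the
#' association midpoint, so the affinity is only bounded from below, the
#' situation expected for weak non-specific sticking.
#'
#' @param series Data frame with columns `concentration` (M), `radius_nm`,
#'   optionally `radius_sd_nm`. At least 4 points spanning a >= 4-fold
#'   concentration range.
#' @param start Optional named list with starting `kd` (M) and `r0` (nm);
#'   defaults `kd` = median concentration, `r0` = smallest radius.
#' @param kd_max Upper bound for Kd, molar (default 1 mM).
#' @return An object of class `dls_fit` with [tidy()] / [glance()] methods.
#' @examples
#' curve <- predict_radius_curve(25e-6, 3.5, c(5, 10, 25, 50, 100) * 1e-6)
#' fit_dls(dplyr::rename(curve, radius_nm = radius_nm))
#' @export
fit_dls <- function(series, start = NULL, kd_max = 1e-3) {
  if (!is.data.frame(series) ||
      !all(c("concentration", "radius_nm") %in% names(series))) {
    abort("`series` must have columns `concentration` and `radius_nm`.",
          class = "clampeq_schema")
  }
  conc <- series$concentration
  r <- series$radius_nm
  check_positive(conc, "concentration")
  check_positive(r, "radius_nm")
  if (length(conc) < 4L || max(conc) / min(conc) < 4) {
    abort("Need >= 4 points spanning at least a 4-fold concentration range.",
          class = "clampeq_invalid_parameter")
  }
  w <- if ("radius_sd_nm" %in% names(series)) 1 / series$radius_sd_nm else
    rep(1, length(r))

  kd0 <- if (!is.null(start$kd)) start$kd else stats::median(conc)
  r00 <- if (!is.null(start$r0)) start$r0 else min(r)
  r00 <- min(max(r00, 0.51), 19.9)

  model_r <- function(kd, r0) r0 * sqrt((1 + sqrt(1 + 4 * conc / kd)) / 2)
  fit <- minpack.lm::nls.lm(
    par = c(log_kd = log(kd0), r0 = r00),
    fn = function(p) w * (model_r(exp(p[["log_kd"]]), p[["r0"]]) - r),
    lower = c(log_kd = log(1e-12), r0 = 0.5),
    upper = c(log_kd = log(kd_max), r0 = 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  kd_hat <- exp(fit$par[["log_kd"]])
  r0_hat <- fit$par[["r0"]]

  se <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], rownames(co))
  }, error = function(e) c(log_kd = NA_real_, r0 = NA_real_))

  low_affinity <- kd_hat >= kd_max * (1 - 1e-6) || kd_hat > max(conc)
  if (low_affinity) {
    warn(sprintf("Fitted Kd (%.3g M) exceeds the sampled concentration range; consistent with non-specific aggregation rather than a defined cross-link.",
                 kd_hat), class = "clampeq_low_affinity")
  }
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(sprintf("DLS fit did not report convergence (info = %d).", fit$info),
         class = "clampeq_numerical")
  }
  dof <- length(r) - 2L
  structure(list(
    kd = kd_hat, r0 = r0_hat,
    std_errors = c(log_kd = unname(se["log_kd"]), r0 = unname(se["r0"])),
    data = tibble(concentration = conc, radius_nm = r,
                  fitted = model_r(kd_hat, r0_hat)),
    low_affinity = low_affinity, converged = converged, info = fit$info,
    deviance = fit$deviance, sigma = sqrt(fit$deviance / max(dof, 1)),
    df.residual = dof, niter = fit$niter
  ), class = "dls_fit")
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("<dls_fit> Kd = %.4g M, r0 = %.3f nm%s\n", x$kd, x$r0,
              if (x$low_affinity) " [low-affinity/aggregation regime]" else ""))
  invisible(x)
}

#' @rdname fit_dls
#' @param x A `dls_fit`.
#' @param ... Unused.
#' @method tidy dls_fit
#' @export
tidy.dls_fit <- function(x, ...) {
  tibble(
    term = c("kd", "r0"),
    estimate = c(x$kd, x$r0),
    std.error = c(x$kd * x$std_errors[["log_kd"]], x$std_errors[["r0"]]),
    unit = c("M", "nm")
  )
}

#' @rdname fit_dls
#' @method glance dls_fit
#' @export
glance.dls_fit <- function(x, ...) {
  tibble(sigma = x$sigma, deviance = x$deviance, df.residual = x$df.residual,
         nobs = nrow(x$data), low_affinity = x$low_affinity,
         converged = x$converged, niter = x$niter)
}
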