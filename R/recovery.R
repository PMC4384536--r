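#' Parameter-recovery study for the one-set-of-sites fitter
#'
#' Simulates `replicates` noisy thermograms at a given titration geometry
#' and generating parameters, fits each with [fit_one_site()], and returns
#' the per-replicate estimates. This is the standard way to ask whether a
#' printed affinity could be recovered from a single titration at the
#' concentrations used.
#'
#' When the design c value \eqn{c = n K_a M_0} is below `low_c_threshold`,
#' the stoichiometry is fixed at its known value rather than fitted: in the
#' low-c regime the isotherm is too shallow to determine `n`, `\Delta H` and
#' `K_a` jointly, and fixing `n` is the accepted treatment of such
#' titrations.
#'
#' @param params Generating [binding_parameters()].
#' @param experiment The [itc_experiment()] geometry.
#' @param noise_fraction Gaussian noise sd on normalized heats as a fraction
#'   of |enthalpy| (default 0.02).
#' @param replicates Number of simulated titrations.
#' @param seed Integer seed for the generator.
#' @param low_c_threshold Design-c below which `n` is fixed (default 10).
#' @return A tibble with one row per replicate: `replicate`, `kd`,
#'   `enthalpy`, `n`, `converged`, `c_value`, and an `n_fixed` logical.
#' @export
itc_recovery_study <- function(params, experiment, noise_fraction = 0.02,
                               replicates = 50, seed = 1,
                               low_c_threshold = 10) {
  design_c <- params$n * params$ka * experiment$cell_conc
  fix_n <- if (design_c < low_c_threshold) params$n else NULL
  sims <- gen_itc(experiment, params, noise_fraction = noise_fraction,
                  replicates = replicates, seed = seed)
  purrr::map_dfr(split(sims, sims$replicate), function(tg) {
    fit <- suppressWarnings(fit_one_site(tg, experiment, fix_n = fix_n))
    p <- fit$parameters
    tibble(replicate = tg$replicate[1], kd = p$kd, enthalpy = p$enthalpy,
           n = p$n, converged = fit$converged, c_value = fit$c_value,
           n_fixed = !is.null(fix_n))
  })
}

#' Parameter-recovery study for the DLS oligomerization fitter
#'
#' Simulates `replicates` noisy radius-concentration series from a
#' generating (Kd, r0) pair and fits each with [fit_dls()].
#'
#' @param kd Generating cross-link dissociation constant, molar.
#' @param r0 Generating monomer spacing, nm.
#' @param concentrations Concentration panel, molar.
#' @param noise_fraction Multiplicative radius noise (default 0.03).
#' @param replicates Number of simulated series.
#' @param seed Integer seed.
#' @return A tibble with one row per replicate: `replicate`, `kd`, `r0`,
#'   `low_affinity`, `converged`.
#' @export
dls_recovery_study <- function(kd, r0,
                               concentrations = c(5, 10, 25, 50, 100) * 1e-6,
                               noise_fraction = 0.03, replicates = 50,
                               seed = 1) {
  sims <- gen_dls(kd, r0, concentrations, noise_fraction = noise_fraction,
                  replicates = replicates, seed = seed)
  purrr::map_dfr(split(sims, sims$replicate), function(s) {
    fit <- suppressWarnings(fit_dls(s[, c("concentration", "radius_nm")]))
    tibble(replicate = s$replicate[1], kd = fit$kd, r0 = fit$r0,
           low_affinity = fit$low_affinity, converged = fit$converged)
  })
}
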