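#' Cumulative heat of the one-set-of-sites (Wiseman) isotherm
#'
#' Total heat evolved in the cell when macromolecule at `mt` and titrant at
#' `xt` equilibrate with `n` identical independent sites of enthalpy
#' `enthalpy` and affinity `1/kd`:
#' \deqn{Q = \frac{n M_t \Delta H V_0}{2}\left[b - \sqrt{b^2 - 4X_t/(nM_t)}\right],
#'       \quad b = 1 + \frac{X_t}{nM_t} + \frac{1}{n K_a M_t}.}
#' Evaluated via the conjugate of the bracket for numerical stability. This
#' is simply \eqn{V_0 \Delta H} times the bound-titrant concentration from
#' the 1:1 quadratic with receptor total \eqn{nM_t}.
#'
#' @param kd Dissociation constant, molar.
#' @param enthalpy Site enthalpy, kcal/mol.
#' @param n Stoichiometry.
#' @param mt Macromolecule concentration in the cell, molar (vectorised).
#' @param xt Titrant concentration in the cell, molar (vectorised).
#' @param cell_volume Active cell volume, litres.
#' @return Cumulative heat in microcalories; zero when `xt = 0`, bounded in
#'   magnitude by `n * mt * enthalpy * cell_volume`.
#' @export
one_site_cumulative_heat <- function(kd, enthalpy, n, mt, xt, cell_volume) {
  check_positive(kd, "kd")
  check_positive(n, "n")
  check_positive(mt, "mt")
  check_positive(xt, "xt", strict = FALSE)
  check_positive(cell_volume, "cell_volume")
  xr <- xt / (n * mt)
  b <- 1 + xr + kd / (n * mt)
  disc <- b^2 - 4 * xr
  if (any(disc < -1e-12)) {
    abort("Negative discriminant in the one-set-of-sites isotherm; inputs are inconsistent.",
          class = "clampeq_internal")
  }
  disc[disc < 0] <- 0
  bracket <- 4 * xr / (b + sqrt(disc))
  q_kcal <- n * mt * enthalpy * cell_volume / 2 * bracket
  q_kcal * 1e9  # kcal -> ucal
}

ndh_from_heats <- function(heat_ucal, injection_volumes, syringe_conc) {
  moles <- injection_volumes * syringe_conc
  (heat_ucal * 1e-9) / moles  # ucal -> kcal, per mole of injectant
}

finish_thermogram <- function(conc, q_ucal, experiment) {
  dv <- experiment$injection_volumes
  v0 <- experiment$cell_volume
  q_prev <- c(0, q_ucal[-length(q_ucal)])
  dq <- q_ucal + (dv / v0) * (q_ucal + q_prev) / 2 - q_prev
  out <- tibble(
    injection = conc$injection,
    volume_uL = dv * 1e6,
    molar_ratio = conc$molar_ratio,
    cumulative_heat_ucal = q_ucal,
    heat_ucal = dq,
    ndh_kcal_per_mol = ndh_from_heats(dq, dv, experiment$syringe_conc)
  )
  class(out) <- c("itc_thermogram", class(out))
  out
}

#' Simulate a one-set-of-sites titration thermogram
#'
#' Forward model for a calorimetric titration: computes cell concentrations
#' after each injection, the cumulative Wiseman heat, and differences it
#' into per-injection heats with the displaced-volume correction
#' \deqn{\Delta Q_i = Q_i + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} - Q_{i-1}.}
#'
#' @param experiment An [itc_experiment()].
#' @param params A [binding_parameters()] row (or anything with `kd`,
#'   `enthalpy`, `n` fields).
#' @return A tibble of class `itc_thermogram` with columns `injection`,
#'   `volume_uL`, `molar_ratio`, `cumulative_heat_ucal`, `heat_ucal` (per
#'   injection, ucal) and `ndh_kcal_per_mol` (heat per mole of injectant).
#' @examples
#' exp <- itc_experiment(cell_conc = 14e-6, syringe_conc = 210e-6)
#' simulate_thermogram(exp, binding_parameters(kd = 457e-9, enthalpy = -10))
#' @export
simulate_thermogram <- function(experiment, params) {
  conc <- titration_concentrations(experiment)
  q <- one_site_cumulative_heat(params$kd, params$enthalpy, params$n,
                                conc$macromolecule, conc$titrant,
                                experiment$cell_volume)
  finish_thermogram(conc, q, experiment)
}

# Free titrant concentration from the multi-site-class mass balance
# Xt = L + Mt * sum_j n_j K_j L / (1 + K_j L), solved by monotone bracketing.
solve_free_titrant <- function(xt, mt, ka, n) {
  if (xt <= 0) return(0)
  f <- function(l) l + mt * sum(n * ka * l / (1 + ka * l)) - xt
  fprime <- function(l) 1 + mt * sum(n * ka / (1 + ka * l)^2)
  # f(0) = -xt < 0, f(xt) >= 0; f strictly increasing
  root <- stats::uniroot(f, c(0, xt), tol = xt * 1e-12, maxiter = 2000L)$root
  # Newton polish to machine precision
  for (i in 1:3) {
    step <- f(root) / fprime(root)
    root <- min(max(root - step, 0), xt)
  }
  if (abs(f(root)) > 1e-8 * xt) {
    abort(sprintf("Free-titrant root finding did not converge (Xt = %.3g M, residual %.3g).",
                  xt, f(root)),
          class = "clampeq_numerical")
  }
  root
}

#' Simulate a thermogram for several independent site classes
#'
#' Models a bivalent titrant binding a bivalent macromolecule as two (or
#' more) independent site classes with separate (Kd, enthalpy, n). Per
#' injection the free titrant L satisfies the mass balance
#' \eqn{X_t = L + M_t \sum_j n_j K_j L/(1+K_j L)} and the cumulative heat is
#' \eqn{Q = V_0 M_t \sum_j n_j \Delta H_j K_j L/(1+K_j L)}. With a single
#' class this reduces exactly to [simulate_thermogram()], as does setting a
#' class's `kd` to `Inf` (zero association). Note that a class with zero
#' *enthalpy* is calorimetrically silent but still binds: it depletes free
#' titrant and thereby shifts the other classes' occupancy, so it does not
#' drop out of the heat curve.
#'
#' @param experiment An [itc_experiment()].
#' @param sites A data frame with one row per site class and columns `kd`
#'   (molar), `enthalpy` (kcal/mol), `n` (sites per macromolecule). Row
#'   order is irrelevant.
#' @return An `itc_thermogram` tibble as in [simulate_thermogram()].
#' @examples
#' exp <- itc_experiment(cell_conc = 7.5e-6, syringe_conc = 150e-6)
#' sites <- tibble::tibble(kd = c(457e-9, 2e-6), enthalpy = c(-10, -5), n = c(1, 1))
#' simulate_two_site_thermogram(exp, sites)
#' @export
simulate_two_site_thermogram <- function(experiment, sites) {
  stopifnot(is.data.frame(sites), all(c("kd", "enthalpy", "n") %in% names(sites)))
  check_positive(sites$kd, "sites$kd")
  check_positive(sites$n, "sites$n", strict = FALSE)
  conc <- titration_concentrations(experiment)
  ka <- 1 / sites$kd
  q <- purrr::map2_dbl(conc$titrant, conc$macromolecule, function(xt, mt) {
    l <- solve_free_titrant(xt, mt, ka, sites$n)
    occ <- ka * l / (1 + ka * l)
    experiment$cell_volume * mt * sum(sites$n * sites$enthalpy * occ) * 1e9
  })
  finish_thermogram(conc, q, experiment)
}
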