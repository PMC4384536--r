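#' Injection schedule for a titration
#'
#' Default schedule for a small-cell titration calorimeter: a small first
#' injection (conventionally discarded from analysis because of syringe-tip
#' diffusion during equilibration) followed by `n` equal injections.
#'
#' @param n Number of main injections.
#' @param volume Volume of each main injection, litres.
#' @param first_volume Volume of the discarded first injection, litres; `NULL`
#'   or 0 omits it.
#' @return Numeric vector of injection volumes in litres.
#' @export
itc_injection_schedule <- function(n = 20, volume = 2e-6, first_volume = 0.4e-6) {
  check_positive(volume, "volume")
  if (is.null(first_volume) || isTRUE(first_volume == 0)) {
    rep(volume, n)
  } else {
    check_positive(first_volume, "first_volume")
    c(first_volume, rep(volume, n))
  }
}

#' Define an ITC titration experiment
#'
#' Bundles the geometry of a calorimetric titration: cell volume, initial
#' macromolecule concentration in the cell, titrant concentration in the
#' syringe, and the injection schedule.
#'
#' @param cell_conc Initial macromolecule concentration in the cell, molar.
#' @param syringe_conc Titrant concentration in the syringe, molar.
#' @param cell_volume Active cell volume, litres (default 200 uL).
#' @param injection_volumes Vector of injection volumes, litres.
#' @param temperature Temperature, kelvin.
#' @return An object of class `itc_experiment`.
#' @examples
#' itc_experiment(cell_conc = 14e-6, syringe_conc = 210e-6)
#' @export
itc_experiment <- function(cell_conc, syringe_conc, cell_volume = 200e-6,
                           injection_volumes = itc_injection_schedule(),
                           temperature = default_temperature()) {
  check_positive(cell_conc, "cell_conc")
  check_positive(syringe_conc, "syringe_conc")
  check_positive(cell_volume, "cell_volume")
  check_positive(injection_volumes, "injection_volumes")
  check_positive(temperature, "temperature")
  if (sum(injection_volumes) >= cell_volume) {
    warn("Cumulative injected volume reaches the cell volume; the displacement correction becomes unreliable.",
         class = "clampeq_overfill")
  }
  structure(
    list(cell_conc = cell_conc, syringe_conc = syringe_conc,
         cell_volume = cell_volume, injection_volumes = injection_volumes,
         temperature = temperature),
    class = "itc_experiment"
  )
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "<itc_experiment> %.3g uM cell (%.0f uL), %.3g uM syringe, %d injections (%.2g uL total)\n",
    x$cell_conc * 1e6, x$cell_volume * 1e6, x$syringe_conc * 1e6,
    length(x$injection_volumes), sum(x$injection_volumes) * 1e6))
  invisible(x)
}

#' One-set-of-sites binding parameters
#'
#' @param kd Dissociation constant, molar.
#' @param enthalpy Binding enthalpy, kcal/mol.
#' @param n Stoichiometry (sites per macromolecule).
#' @param temperature Temperature, kelvin.
#' @return A one-row tibble of class `binding_parameters` with columns `kd`,
#'   `ka`, `enthalpy`, `n`, `temperature_K`.
#' @export
binding_parameters <- function(kd, enthalpy, n = 1,
                               temperature = default_temperature()) {
  check_positive(kd, "kd")
  check_positive(n, "n")
  check_positive(temperature, "temperature")
  if (!is.numeric(enthalpy) || is.na(enthalpy)) {
    abort("`enthalpy` must be a finite number (kcal/mol).",
          class = "clampeq_invalid_parameter")
  }
  out <- tibble(kd = kd, ka = 1 / kd, enthalpy = enthalpy, n = n,
                temperature_K = temperature)
  class(out) <- c("binding_parameters", class(out))
  out
}

#' Cell concentrations after each injection
#'
#' Applies the standard perfusion displacement correction for a
#' constant-volume cell: with cumulative injected volume \eqn{v} into active
#' volume \eqn{V_0},
#' \deqn{M_t = M_0\frac{1 - v/2V_0}{1 + v/2V_0}, \qquad
#'       X_t = X_0\frac{v/V_0}{1 + v/2V_0}.}
#'
#' @param experiment An [itc_experiment()].
#' @return A tibble with one row per injection: `injection`, `volume`
#'   (litres), `cumulative_volume`, `macromolecule` (`Mt`, molar, strictly
#'   decreasing), `titrant` (`Xt`, molar) and `molar_ratio` (`Xt/Mt`).
#' @export
titration_concentrations <- function(experiment) {
  stopifnot(inherits(experiment, "itc_experiment"))
  v0 <- experiment$cell_volume
  v <- cumsum(experiment$injection_volumes)
  mt <- experiment$cell_conc * (1 - v / (2 * v0)) / (1 + v / (2 * v0))
  xt <- experiment$syringe_conc * (v / v0) / (1 + v / (2 * v0))
  tibble(
    injection = seq_along(v),
    volume = experiment$injection_volumes,
    cumulative_volume = v,
    macromolecule = mt,
    titrant = xt,
    molar_ratio = xt / mt
  )
}
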