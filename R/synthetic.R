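# Each generator draws from its own stream derived from (seed, operation),
# so two generators called with the same seed do not share noise, and the
# caller's global RNG state is left untouched.
with_op_seed <- function(seed, op, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  derived <- (abs(as.integer(seed)) %% 1000003L) * 1013L + (h %% 100003L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derived)
  force(code)
}

#' Generate synthetic ITC thermograms
#'
#' Forward-simulates a titration with [simulate_thermogram()] (one site
#' class) or [simulate_two_site_thermogram()] (a data frame of site
#' classes), then adds independent Gaussian noise to the normalized heats
#' with standard deviation `noise_fraction * |enthalpy|` (for multiple site
#' classes, the largest |enthalpy|). Per-injection heats are kept consistent
#' with the noisy normalized heats. Output is deterministic in `seed`.
#'
#' @param experiment An [itc_experiment()].
#' @param params A [binding_parameters()] row, or a data frame of site
#'   classes for the multivalent model.
#' @param noise_fraction Noise standard deviation as a fraction of
#'   |enthalpy| (default 0.02).
#' @param replicates Number of independent noise draws.
#' @param seed Integer seed.
#' @return A tibble: the thermogram columns plus `replicate`.
#' @export
gen_itc <- function(experiment, params, noise_fraction = 0.02,
                    replicates = 1, seed = 1) {
  check_positive(noise_fraction, "noise_fraction", strict = FALSE)
  check_positive(replicates, "replicates")
  base <- if (is.data.frame(params) && nrow(params) > 1L) {
    simulate_two_site_thermogram(experiment, params)
  } else {
    simulate_thermogram(experiment, params)
  }
  sd_ndh <- noise_fraction * max(abs(params$enthalpy))
  moles <- experiment$injection_volumes * experiment$syringe_conc
  with_op_seed(seed, "gen_itc", {
    purrr::map_dfr(seq_len(replicates), function(rep) {
      tg <- base
      tg$ndh_kcal_per_mol <- tg$ndh_kcal_per_mol +
        stats::rnorm(nrow(tg), 0, sd_ndh)
      tg$heat_ucal <- tg$ndh_kcal_per_mol * moles * 1e9
      dplyr::mutate(tg, replicate = rep, .before = 1)
    })
  })
}

#' Generate a synthetic DLS radius-concentration series
#'
#' Evaluates [predict_radius_curve()] and applies multiplicative Gaussian
#' noise `radius * (1 + N(0, noise_fraction))` to each radius.
#'
#' @param kd Cross-link dissociation constant, molar.
#' @param r0 Monomer spacing, nm.
#' @param concentrations Concentration panel, molar; the default
#'   `{5, 10, 25, 50, 100}` uM brackets the regime where complexin-SNAREΔ60
#'   oligomerization sets in.
#' @param noise_fraction Fractional radius noise (default 0.03).
#' @param replicates Number of independent noise draws.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate`, `concentration`, `radius_nm`.
#' @export
gen_dls <- function(kd, r0, concentrations = c(5, 10, 25, 50, 100) * 1e-6,
                    noise_fraction = 0.03, replicates = 1, seed = 1) {
  check_positive(noise_fraction, "noise_fraction", strict = FALSE)
  check_positive(replicates, "replicates")
  curve <- predict_radius_curve(kd, r0, concentrations)
  with_op_seed(seed, "gen_dls", {
    purrr::map_dfr(seq_len(replicates), function(rep) {
      tibble(replicate = rep,
             concentration = curve$concentration,
             radius_nm = curve$radius_nm *
               (1 + stats::rnorm(nrow(curve), 0, noise_fraction)))
    })
  })
}

#' Generate donor-only and donor-acceptor emission spectra
#'
#' Builds a Gaussian donor emission band on a 410-600 nm grid and a
#' donor-acceptor spectrum scaled so that its integrated intensity is
#' `(1 - target_efficiency)` times the donor-only area (uniform quenching,
#' so the ratio holds in any window). Optional additive noise, truncated at
#' zero to keep intensities physical.
#'
#' @param target_efficiency FRET efficiency to emulate, in `[0, 1)`.
#' @param peak_nm,width_nm Centre and standard deviation of the donor band,
#'   nm. Defaults place the band inside the default 410-470 nm integration
#'   window.
#' @param noise_fraction Additive noise sd as a fraction of the peak
#'   intensity (default 0).
#' @param grid Wavelength grid, nm (default 410-600 in 1 nm steps).
#' @param seed Integer seed.
#' @return A list with tibbles `donor_only` and `donor_acceptor`, each with
#'   columns `wavelength_nm`, `intensity`.
#' @export
gen_spectra <- function(target_efficiency, peak_nm = 440, width_nm = 15,
                        noise_fraction = 0, grid = seq(410, 600, by = 1),
                        seed = 1) {
  if (!is.numeric(target_efficiency) || target_efficiency < 0 ||
      target_efficiency >= 1) {
    abort("`target_efficiency` must lie in [0, 1).",
          class = "clampeq_invalid_parameter")
  }
  check_positive(noise_fraction, "noise_fraction", strict = FALSE)
  peak <- 1000
  band <- peak * exp(-(grid - peak_nm)^2 / (2 * width_nm^2))
  with_op_seed(seed, "gen_spectra", {
    noisy <- function(y) {
      pmax(y + stats::rnorm(length(y), 0, noise_fraction * peak), 0)
    }
    list(
      donor_only = tibble(wavelength_nm = grid, intensity = noisy(band)),
      donor_acceptor = tibble(wavelength_nm = grid,
                              intensity = noisy((1 - target_efficiency) * band))
    )
  })
}
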