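#' FRET efficiency from donor quenching
#'
#' Compares the donor emission band with and without acceptor:
#' \deqn{E = 1 - \frac{\int F_{DA}}{\int F_D}} over an integration window
#' chosen to isolate the donor band (default 410-470 nm, covering the bimane
#' emission within a 410-600 nm scan). Integrals are trapezoidal on the
#' shared wavelength grid; spectra on different grids are refused rather
#' than silently resampled.
#'
#' @param donor_only,donor_acceptor Emission spectra: data frames with
#'   columns `wavelength_nm` (strictly increasing) and `intensity` (>= 0).
#' @param window Length-2 numeric, integration window in nm.
#' @return A one-row tibble with `efficiency` (clamped to `[0, 1]`),
#'   `efficiency_raw`, `donor_area`, `da_area` and `out_of_range` (TRUE when
#'   the raw value fell outside `[0, 1]`).
#' @export
fret_efficiency <- function(donor_only, donor_acceptor, window = c(410, 470)) {
  check_spectrum <- function(s, name) {
    if (!is.data.frame(s) ||
        !all(c("wavelength_nm", "intensity") %in% names(s))) {
      abort(sprintf("`%s` must have columns `wavelength_nm` and `intensity`.",
                    name), class = "clampeq_schema")
    }
    if (is.unsorted(s$wavelength_nm, strictly = TRUE)) {
      abort(sprintf("`%s` wavelengths must be strictly increasing.", name),
            class = "clampeq_invalid_parameter")
    }
    if (any(s$intensity < 0)) {
      abort(sprintf("`%s` intensities must be non-negative.", name),
            class = "clampeq_invalid_parameter")
    }
    s
  }
  check_spectrum(donor_only, "donor_only")
  check_spectrum(donor_acceptor, "donor_acceptor")
  stopifnot(length(window) == 2L, window[1] < window[2])

  in_win <- function(s) s[s$wavelength_nm >= window[1] &
                          s$wavelength_nm <= window[2], ]
  d <- in_win(donor_only)
  da <- in_win(donor_acceptor)
  if (nrow(d) != nrow(da) || !isTRUE(all.equal(d$wavelength_nm,
                                               da$wavelength_nm))) {
    abort("Spectra are on different wavelength grids within the window; resampling is not performed.",
          class = "clampeq_grid_mismatch")
  }
  if (nrow(d) < 2L) {
    abort("Fewer than 2 samples inside the integration window.",
          class = "clampeq_invalid_parameter")
  }
  a_d <- trapz(d$wavelength_nm, d$intensity)
  if (a_d <= 0) {
    abort("Donor-only spectrum has zero integrated intensity in the window.",
          class = "clampeq_invalid_parameter")
  }
  a_da <- trapz(da$wavelength_nm, da$intensity)
  e_raw <- 1 - a_da / a_d
  tibble(
    efficiency = min(max(e_raw, 0), 1),
    efficiency_raw = e_raw,
    donor_area = a_d,
    da_area = a_da,
    out_of_range = e_raw < 0 || e_raw > 1
  )
}

#' Inter-probe distance from a FRET efficiency
#'
#' Inverts the Forster relation \eqn{E = 1/(1 + (r/R_0)^6)}:
#' \eqn{r = R_0 (1/E - 1)^{1/6}}. `E = 0.5` maps to `r = R0`; the map is a
#' monotone decreasing bijection on (0, 1).
#'
#' @param efficiency Transfer efficiency, strictly inside (0, 1).
#' @param r0 Forster radius of the dye pair, angstrom (e.g. ~27 for
#'   stilbene/bimane, ~38 for bimane/Oregon Green).
#' @param f_label Optional labeling efficiency in (0, 1]; when supplied the
#'   measured efficiency is corrected as `E / f_label` before inversion.
#' @return Distance in angstrom.
#' @examples
#' fret_distance(0.15, r0 = 27)
#' @export
fret_distance <- function(efficiency, r0, f_label = NULL) {
  check_positive(r0, "r0")
  e <- efficiency
  if (!is.null(f_label)) {
    check_positive(f_label, "f_label")
    if (any(f_label > 1)) {
      abort("`f_label` cannot exceed 1.", class = "clampeq_invalid_parameter")
    }
    e <- e / f_label
  }
  if (!is.numeric(e) || anyNA(e) || any(e <= 0) || any(e >= 1)) {
    abort("`efficiency` must lie strictly inside (0, 1); 0 and 1 map to infinite and zero distance.",
          class = "clampeq_invalid_parameter")
  }
  r0 * (1 / e - 1)^(1 / 6)
}

#' Forward Forster relation
#'
#' @param distance Inter-probe distance, angstrom (> 0).
#' @param r0 Forster radius, angstrom.
#' @return Transfer efficiency \eqn{1/(1+(r/R_0)^6)} in (0, 1).
#' @export
fret_efficiency_from_distance <- function(distance, r0) {
  check_positive(distance, "distance")
  check_positive(r0, "r0")
  1 / (1 + (distance / r0)^6)
}
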