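require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "clampeq_schema")
  }
  invisible(df)
}

#' Read a thermogram CSV
#'
#' Expects columns `injection`, `volume_uL`, `heat_ucal` (normalized heats
#' are recomputed from the experiment's syringe concentration when absent).
#'
#' @param path CSV file path.
#' @param experiment Optional [itc_experiment()]; when given,
#'   `ndh_kcal_per_mol` and `molar_ratio` are (re)computed from it.
#' @return An `itc_thermogram` tibble.
#' @export
read_thermogram <- function(path, experiment = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("injection", "volume_uL", "heat_ucal"),
                  sprintf("Thermogram file '%s'", path))
  if (!is.null(experiment)) {
    conc <- titration_concentrations(experiment)
    if (nrow(df) != nrow(conc)) {
      abort("Thermogram row count does not match the experiment's injection schedule.",
            class = "clampeq_schema")
    }
    df$molar_ratio <- conc$molar_ratio
    df$ndh_kcal_per_mol <- ndh_from_heats(df$heat_ucal, df$volume_uL * 1e-6,
                                          experiment$syringe_conc)
  }
  out <- as_tibble(df)
  class(out) <- c("itc_thermogram", class(out))
  out
}

#' Write a thermogram CSV
#'
#' @param thermogram An `itc_thermogram` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(thermogram, path) {
  require_columns(thermogram, c("injection", "volume_uL", "heat_ucal"),
                  "Thermogram")
  readr::write_csv(thermogram, path)
  invisible(path)
}

#' Read a DLS series CSV
#'
#' Expects columns `conc_uM`, `radius_nm` and optionally `radius_sd_nm`;
#' concentrations are converted to molar.
#'
#' @param path CSV file path.
#' @return A tibble with `concentration` (M), `radius_nm`, and
#'   `radius_sd_nm` when present.
#' @export
read_dls_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("conc_uM", "radius_nm"),
                  sprintf("DLS file '%s'", path))
  out <- tibble(concentration = df$conc_uM * 1e-6, radius_nm = df$radius_nm)
  if ("radius_sd_nm" %in% names(df)) out$radius_sd_nm <- df$radius_sd_nm
  out
}

#' Read an emission spectrum CSV
#'
#' Expects columns `wavelength_nm`, `intensity`.
#'
#' @param path CSV file path.
#' @return A tibble with `wavelength_nm`, `intensity`.
#' @export
read_spectrum <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("wavelength_nm", "intensity"),
                  sprintf("Spectrum file '%s'", path))
  as_tibble(df)
}

write_report_json <- function(report, out) {
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(out)
}

#' Run a one-set-of-sites ITC analysis end to end
#'
#' Reads (or accepts) a thermogram, fits the one-set-of-sites model, and
#' assembles a table of N, enthalpy, Kd, free energy and entropy term with
#' standard errors — the shape of a calorimetry results table.
#'
#' @param input Path to a thermogram CSV or an `itc_thermogram` data frame.
#' @param experiment The [itc_experiment()] describing the titration.
#' @param out Optional path for a machine-readable JSON report.
#' @param ... Passed to [fit_one_site()].
#' @return A list of class `clampeq_report` with elements `table` (tidy
#'   parameter tibble), `glance`, and `fit`.
#' @export
run_itc_analysis <- function(input, experiment, out = NULL, ...) {
  tg <- if (is.character(input)) read_thermogram(input, experiment) else input
  fit <- fit_one_site(tg, experiment, ...)
  table <- tidy(fit)
  report <- structure(list(table = table, glance = glance(fit), fit = fit),
                      class = "clampeq_report")
  write_report_json(list(analysis = "itc_one_site",
                         parameters = as.list(tibble::deframe(
                           table[, c("term", "estimate")])),
                         c_value = fit$c_value, c_warning = fit$c_warning),
                    out)
  report
}

#' Tabulate blocking-site saturation across ligand excesses
#'
#' For a receptor held at `receptor_total`, reports the percent occupancy
#' achieved by each fold excess of a blocking ligand of affinity `kd` —
#' the calculation behind the claim that 1.5x excess of the blocking
#' fragment leaves the central-helix site ~96% occupied.
#'
#' @param receptor_total Receptor concentration, molar.
#' @param excess_folds Vector of molar excess values (> 0).
#' @param kd Dissociation constant of the blocking interaction, molar.
#' @param out Optional JSON report path.
#' @return A tibble with `excess_fold` and `saturation_percent` (monotone
#'   increasing).
#' @export
run_saturation_report <- function(receptor_total, excess_folds, kd,
                                  out = NULL) {
  tab <- tibble(
    excess_fold = excess_folds,
    saturation_percent = saturation_percent(receptor_total, excess_folds, kd)
  )
  write_report_json(list(analysis = "saturation",
                         receptor_total_M = receptor_total, kd_M = kd,
                         table = tab), out)
  tab
}

#' Run a DLS oligomerization analysis end to end
#'
#' @param input Path to a DLS CSV (see [read_dls_series()]) or a data frame
#'   with `concentration` and `radius_nm`.
#' @param out Optional JSON report path.
#' @param ... Passed to [fit_dls()].
#' @return A `clampeq_report` list with `table`, `glance`, `fit`.
#' @export
run_dls_analysis <- function(input, out = NULL, ...) {
  series <- if (is.character(input)) read_dls_series(input) else input
  fit <- fit_dls(series, ...)
  table <- tidy(fit)
  report <- structure(list(table = table, glance = glance(fit), fit = fit),
                      class = "clampeq_report")
  write_report_json(list(analysis = "dls_oligomer",
                         kd_M = fit$kd, r0_nm = fit$r0,
                         low_affinity = fit$low_affinity), out)
  report
}

#' Run a donor-quenching FRET analysis end to end
#'
#' @param donor_only,donor_acceptor Spectrum CSV paths (see
#'   [read_spectrum()]) or data frames.
#' @param r0 Forster radius of the dye pair, angstrom.
#' @param window Integration window, nm.
#' @param out Optional JSON report path.
#' @return A one-row tibble with `efficiency`, `distance_A`, `r0`, and the
#'   efficiency bookkeeping columns.
#' @export
run_fret_analysis <- function(donor_only, donor_acceptor, r0,
                              window = c(410, 470), out = NULL) {
  d <- if (is.character(donor_only)) read_spectrum(donor_only) else donor_only
  da <- if (is.character(donor_acceptor)) read_spectrum(donor_acceptor) else
    donor_acceptor
  eff <- fret_efficiency(d, da, window)
  dist <- if (eff$efficiency > 0 && eff$efficiency < 1)
    fret_distance(eff$efficiency, r0) else NA_real_
  tab <- dplyr::mutate(eff, r0 = r0, distance_A = dist)
  write_report_json(list(analysis = "fret_donor_quenching",
                         efficiency = eff$efficiency, r0_A = r0,
                         distance_A = dist), out)
  tab
}

#' @export
print.clampeq_report <- function(x, ...) {
  print(x$table)
  invisible(x)
}
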