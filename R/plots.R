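#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
NULL

#' @export
ggplot2::autoplot

#' Plot a titration thermogram
#'
#' Normalized heat per mole of injectant against the cumulative molar ratio,
#' the conventional lower panel of an ITC figure.
#'
#' @param object An `itc_thermogram` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_thermogram
#' @export
autoplot.itc_thermogram <- function(object, ...) {
  ggplot(object, aes(.data$molar_ratio, .data$ndh_kcal_per_mol)) +
    geom_point(shape = 21, fill = "grey30") +
    labs(x = "Molar ratio (titrant / macromolecule)",
         y = "Normalized heat (kcal/mol of injectant)")
}

#' Plot an ITC fit
#'
#' Observed normalized heats with the fitted one-set-of-sites isotherm.
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$molar_ratio)) +
    geom_point(aes(y = .data$observed), shape = 21, fill = "grey30") +
    geom_line(aes(y = .data$fitted), colour = "red3") +
    labs(x = "Molar ratio (titrant / macromolecule)",
         y = "Normalized heat (kcal/mol of injectant)")
}

#' Plot a predicted radius-concentration curve
#'
#' @param object A `dls_curve` tibble from [predict_radius_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dls_curve
#' @export
autoplot.dls_curve <- function(object, ...) {
  ggplot(object, aes(.data$concentration * 1e6, .data$radius_nm)) +
    geom_line() +
    labs(x = "Complex concentration (uM)", y = "Mean radius (nm)")
}

#' Plot a DLS oligomerization fit
#'
#' @param object A `dls_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dls_fit
#' @export
autoplot.dls_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$concentration * 1e6)) +
    geom_point(aes(y = .data$radius_nm), shape = 21, fill = "grey30") +
    geom_line(aes(y = .data$fitted), colour = "red3") +
    labs(x = "Complex concentration (uM)", y = "Mean radius (nm)")
}

#' Overlay donor-only and donor-acceptor emission spectra
#'
#' @param donor_only,donor_acceptor Spectra tibbles
#'   (`wavelength_nm`, `intensity`).
#' @param window Optional integration window to shade, nm.
#' @return A ggplot.
#' @export
plot_spectra <- function(donor_only, donor_acceptor, window = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(donor_only, sample = "donor only"),
    dplyr::mutate(donor_acceptor, sample = "donor + acceptor")
  )
  p <- ggplot(df, aes(.data$wavelength_nm, .data$intensity,
                      colour = .data$sample)) +
    geom_line() +
    labs(x = "Wavelength (nm)", y = "Intensity (a.u.)", colour = NULL)
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  p
}
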