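#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Gas constant in kcal mol^-1 K^-1 (Origin/Microcal energy convention).
RGAS_KCAL <- 1.987e-3

#' Default analysis temperature
#'
#' All thermodynamic conversions default to 25 degrees C (298.15 K), the
#' temperature at which the fluorescence measurements were made; the same
#' value is adopted for calorimetry unless overridden.
#'
#' @return Temperature in kelvin.
#' @export
default_temperature <- function() 298.15

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name),
          class = "clampeq_invalid_parameter")
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    abort(sprintf("`%s` must be %s.", name,
                  if (strict) "strictly positive" else "non-negative"),
          class = "clampeq_invalid_parameter")
  }
  invisible(x)
}

# Trapezoidal quadrature on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
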