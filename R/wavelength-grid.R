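#' Wavelength grid for an excitation-emission matrix
#'
#' A `wavelength_grid` holds the two wavelength axes on which an EEM is
#' measured: the excitation axis and the emission axis, both in nanometres.
#' Each axis must be strictly increasing with a constant step (instruments
#' scan on a regular lattice; the study grid uses a 5 nm step on both axes).
#'
#' @param excitation Numeric vector of excitation wavelengths (nm),
#'   strictly increasing, uniform step.
#' @param emission Numeric vector of emission wavelengths (nm),
#'   strictly increasing, uniform step.
#'
#' @return An object of class `wavelength_grid` with elements `excitation`
#'   and `emission`.
#' @examples
#' g <- default_grid()
#' length(g$excitation) # 36
#' length(g$emission)   # 57
#' @export
wavelength_grid <- function(excitation, emission) {
  check_axis(excitation, "excitation")
  check_axis(emission, "emission")
  structure(list(excitation = as.numeric(excitation),
                 emission = as.numeric(emission)),
            class = "wavelength_grid")
}

check_axis <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L)
    stop(sprintf("grid error: %s axis must be numeric with >= 2 points", name),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("grid error: %s axis contains non-finite values", name),
         call. = FALSE)
  d <- diff(x)
  if (any(d <= 0))
    stop(sprintf("grid error: %s axis must be strictly increasing", name),
         call. = FALSE)
  if (max(d) - min(d) > 1e-8 * max(abs(x)))
    stop(sprintf("grid error: %s axis step is not uniform", name),
         call. = FALSE)
  invisible(x)
}

#' Default fingerprint-region grid
#'
#' The fluorescence fingerprint region used throughout the package:
#' excitation 200-375 nm and emission 270-550 nm, both at a 5 nm step
#' (36 excitation x 57 emission points).
#'
#' @param ex_step,em_step Axis step in nm (default 5).
#' @return A [wavelength_grid()].
#' @export
default_grid <- function(ex_step = 5, em_step = 5) {
  wavelength_grid(excitation = seq(200, 375, by = ex_step),
                  emission = seq(270, 550, by = em_step))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength_grid: excitation %g-%g nm (%d pts), emission %g-%g nm (%d pts)\n",
              min(x$excitation), max(x$excitation), length(x$excitation),
              min(x$emission), max(x$emission), length(x$emission)))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$excitation, b$excitation, tolerance = 0)) &&
    isTRUE(all.equal(a$emission, b$emission, tolerance = 0))
}
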