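#' Chemical-shift grid for 1H-NMR spectra
#'
#' A uniformly spaced grid of chemical shifts (ppm) on which all spectra,
#' basis spectra and attribution score vectors in this package live. The
#' spectrometer frequency ties the ppm axis to Hz: 1 ppm corresponds to
#' \code{freq_mhz} Hz, so linewidths and J-couplings given in Hz can be
#' converted to ppm.
#'
#' Defaults correspond to a 400-MHz proton spectrum restricted to the
#' metabolite signal region, 0.48 to 9.52 ppm, sampled at 39,500 points.
#'
#' @param ppm_min Lower edge of the window (ppm).
#' @param ppm_max Upper edge of the window (ppm). Must exceed `ppm_min`.
#' @param n_points Number of grid points (at least 2).
#' @param freq_mhz Spectrometer frequency in MHz.
#'
#' @return An object of class `nmr_grid`.
#' @examples
#' g <- nmr_grid(0, 10, 11, 400)
#' grid_spacing(g)  # exactly 1 ppm
#' @export
nmr_grid <- function(ppm_min = 0.48, ppm_max = 9.52, n_points = 39500,
                     freq_mhz = 400) {
  if (!is.numeric(ppm_min) || !is.numeric(ppm_max) || ppm_min >= ppm_max)
    stop("`ppm_min` must be strictly less than `ppm_max`")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("`n_points` must be an integer >= 2")
  if (!is.numeric(freq_mhz) || freq_mhz <= 0)
    stop("`freq_mhz` must be positive")
  structure(
    list(ppm_min = as.numeric(ppm_min), ppm_max = as.numeric(ppm_max),
         n_points = n_points, freq_mhz = as.numeric(freq_mhz)),
    class = "nmr_grid")
}

#' @export
print.nmr_grid <- function(x, ...) {
  cat(sprintf("<nmr_grid> %g to %g ppm, %d points (%.4g ppm/pt), %g MHz\n",
              x$ppm_min, x$ppm_max, x$n_points, grid_spacing(x), x$freq_mhz))
  invisible(x)
}

#' Grid spacing in ppm per point
#' @param grid An `nmr_grid`.
#' @return Spacing between adjacent grid points (ppm).
#' @export
grid_spacing <- function(grid) {
  (grid$ppm_max - grid$ppm_min) / (grid$n_points - 1)
}

#' Chemical-shift axis of a grid
#' @param grid An `nmr_grid`.
#' @return Numeric vector of length `n_points`, ascending in ppm.
#' @export
ppm_axis <- function(grid) {
  seq(grid$ppm_min, grid$ppm_max, length.out = grid$n_points)
}

#' Convert Hz to ppm on a grid
#' @param grid An `nmr_grid`.
#' @param hz Frequency offset(s) in Hz.
#' @return Offset(s) in ppm.
#' @export
hz_to_ppm <- function(grid, hz) hz / grid$freq_mhz

#' Nearest grid index of a chemical shift
#' @param grid An `nmr_grid`.
#' @param ppm Chemical shift(s) in ppm.
#' @return Integer index (1-based) of the nearest grid point.
#' @export
ppm_to_index <- function(grid, ppm) {
  idx <- round((ppm - grid$ppm_min) / grid_spacing(grid)) + 1
  as.integer(pmin(pmax(idx, 1L), grid$n_points))
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$ppm_min - b$ppm_min) < tol &&
    abs(a$ppm_max - b$ppm_max) < tol &&
    abs(a$freq_mhz - b$freq_mhz) < tol
}

#' An intensity vector on a chemical-shift grid
#'
#' @param grid An `nmr_grid`.
#' @param intensities Numeric vector of length `grid$n_points`; all values
#'   must be finite. Units are arbitrary intensity units.
#' @return An object of class `nmr_spectrum` with fields `grid` and
#'   `intensities`.
#' @export
nmr_spectrum <- function(grid, intensities) {
  stopifnot(inherits(grid, "nmr_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop(sprintf("intensity vector has length %d but grid has %d points",
                 length(intensities), grid$n_points))
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite")
  structure(list(grid = grid, intensities = intensities),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %g to %g ppm, max intensity %.4g\n",
              x$grid$n_points, x$grid$ppm_min, x$grid$ppm_max,
              max(x$intensities)))
  invisible(x)
}

#' Trapezoidal integral of a spectrum over its ppm axis
#' @param spectrum An `nmr_spectrum` (or numeric vector with `grid` given).
#' @param grid Grid to use when `spectrum` is a bare vector.
#' @return Integral in intensity*ppm units.
#' @export
spectrum_integral <- function(spectrum, grid = NULL) {
  if (inherits(spectrum, "nmr_spectrum")) {
    y <- spectrum$intensities
    grid <- spectrum$grid
  } else y <- as.numeric(spectrum)
  h <- grid_spacing(grid)
  h * (sum(y) - (y[1] + y[length(y)]) / 2)
}

#' Plot a spectrum with the conventional reversed ppm axis
#' @param x An `nmr_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nmr_spectrum <- function(x, ...) {
  graphics::plot(ppm_axis(x$grid), x$intensities, type = "l",
                 xlim = c(x$grid$ppm_max, x$grid$ppm_min),
                 xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  invisible(x)
}
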