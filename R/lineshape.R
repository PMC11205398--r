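#' Sample a Lorentzian line on a grid
#'
#' FT-NMR lines of exponentially decaying FIDs are Lorentzian. The line is
#' parameterised by its centre (ppm), full width at half maximum (Hz,
#' converted to ppm through the grid's spectrometer frequency) and total
#' area, so that L(d) = area * (g/pi) / ((d - center)^2 + g^2) with
#' g = fwhm_ppm / 2. The analytic integral over the whole real line equals
#' `area`; on a finite window a small tail fraction is truncated.
#'
#' @param center Line centre in ppm; must lie inside the grid window.
#' @param fwhm_hz Full width at half maximum in Hz (> 0).
#' @param area Integrated line area (intensity * ppm).
#' @param grid An [nmr_grid()].
#' @return Numeric intensity vector of length `grid$n_points`.
#' @export
lorentzian_line <- function(center, fwhm_hz, area, grid) {
  stopifnot(inherits(grid, "nmr_grid"))
  if (fwhm_hz <= 0) stop("`fwhm_hz` must be positive")
  if (center < grid$ppm_min || center > grid$ppm_max)
    stop(sprintf("line centre %.4g ppm lies outside the grid window [%g, %g]",
                 center, grid$ppm_min, grid$ppm_max))
  g <- hz_to_ppm(grid, fwhm_hz) / 2
  d <- ppm_axis(grid) - center
  area * (g / pi) / (d^2 + g^2)
}

#' Multiplet definition
#'
#' Describes one J-coupled multiplet of an analyte: a set of Lorentzian
#' lines centred on `center`, spaced by the coupling constant `J` (Hz) and
#' weighted by the binomial row for the standard patterns (singlet 1;
#' doublet 1 1; triplet 1 2 1; quartet 1 3 3 1). A `custom` pattern takes
#' explicit lines as a two-column matrix of (offset ppm, relative weight).
#'
#' @param center Multiplet centre (ppm).
#' @param pattern One of `"singlet"`, `"doublet"`, `"triplet"`, `"quartet"`,
#'   `"custom"`.
#' @param J Coupling constant in Hz (ignored for singlets).
#' @param fwhm_hz Linewidth (FWHM, Hz) of each component line.
#' @param n_protons Number of equivalent protons carried by the multiplet;
#'   the multiplet's total area per mM is `n_protons` times the calibration
#'   constant.
#' @param custom_lines For `pattern = "custom"`: matrix/data.frame with
#'   columns offset (ppm, relative to `center`) and weight.
#' @return An object of class `nmr_multiplet`.
#' @export
multiplet <- function(center, pattern = c("singlet", "doublet", "triplet",
                                          "quartet", "custom"),
                      J = 0, fwhm_hz = 0.8, n_protons = 1,
                      custom_lines = NULL) {
  pattern <- match.arg(pattern)
  if (fwhm_hz <= 0) stop("`fwhm_hz` must be positive")
  if (n_protons < 1) stop("`n_protons` must be at least 1")
  if (pattern == "custom") {
    if (is.null(custom_lines)) stop("`custom` pattern requires `custom_lines`")
    custom_lines <- as.matrix(custom_lines)
    if (ncol(custom_lines) != 2) stop("`custom_lines` needs two columns")
  }
  structure(list(center = center, pattern = pattern, J = J,
                 fwhm_hz = fwhm_hz, n_protons = n_protons,
                 custom_lines = custom_lines),
            class = "nmr_multiplet")
}

#' Component lines of a multiplet
#'
#' @param m An [multiplet()].
#' @param freq_mhz Spectrometer frequency, used to convert J (Hz) to ppm.
#' @return Data frame with columns `ppm` (absolute line position) and
#'   `weight` (fraction of the multiplet area, summing to 1).
#' @export
multiplet_lines <- function(m, freq_mhz) {
  stopifnot(inherits(m, "nmr_multiplet"))
  if (m$pattern == "custom") {
    off <- m$custom_lines[, 1]
    w <- m$custom_lines[, 2]
  } else {
    nl <- match(m$pattern, c("singlet", "doublet", "triplet", "quartet"))
    w <- choose(nl - 1, 0:(nl - 1))
    off <- ((0:(nl - 1)) - (nl - 1) / 2) * m$J / freq_mhz
  }
  data.frame(ppm = m$center + off, weight = w / sum(w))
}

#' Synthesize a per-mM basis spectrum from multiplet definitions
#'
#' Sums Lorentzian lines for every multiplet of an analyte, scaled so that
#' the total area equals `calibration` times the total proton count: the
#' result is the unit (1 mM) spectrum of the analyte. Area is conserved up
#' to the Lorentzian tail fraction truncated by the finite window.
#'
#' @param analyte Analyte name.
#' @param multiplets List of [multiplet()] objects (at least one).
#' @param grid An [nmr_grid()].
#' @param calibration Area (intensity * ppm) contributed by one proton of a
#'   1 mM analyte. Arbitrary units; only ratios matter. Default 1.
#' @return An object of class `nmr_basis` with fields `analyte`, `grid`,
#'   `unit_intensities` and `n_protons`.
#' @export
synthesize_basis <- function(analyte, multiplets, grid, calibration = 1) {
  stopifnot(inherits(grid, "nmr_grid"))
  if (length(multiplets) < 1) stop("need at least one multiplet")
  v <- numeric(grid$n_points)
  np_total <- 0
  for (m in multiplets) {
    stopifnot(inherits(m, "nmr_multiplet"))
    lines <- multiplet_lines(m, grid$freq_mhz)
    area_tot <- calibration * m$n_protons
    for (i in seq_len(nrow(lines)))
      v <- v + lorentzian_line(lines$ppm[i], m$fwhm_hz, area_tot * lines$weight[i],
                               grid)
    np_total <- np_total + m$n_protons
  }
  structure(list(analyte = analyte, grid = grid, unit_intensities = v,
                 n_protons = np_total),
            class = "nmr_basis")
}

#' @export
print.nmr_basis <- function(x, ...) {
  cat(sprintf("<nmr_basis> %s: %d protons, peak %.4g per mM on %d points\n",
              x$analyte, x$n_protons, max(x$unit_intensities),
              x$grid$n_points))
  invisible(x)
}

#' Read a multiplet table from JSON
#'
#' The JSON maps analyte names to arrays of multiplet records with fields
#' `center`, `pattern`, `J`, `fwhm`, `n_protons` (and optionally
#' `custom_lines`).
#'
#' @param path Path to a JSON multiplet table.
#' @return Named list of multiplet lists, suitable for [synthesize_basis()].
#' @export
read_multiplet_table <- function(path) {
  tbl <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(tbl, function(ms) lapply(ms, function(r) {
    multiplet(center = r$center, pattern = r$pattern,
              J = if (is.null(r$J)) 0 else r$J,
              fwhm_hz = r$fwhm, n_protons = r$n_protons,
              custom_lines = if (is.null(r$custom_lines)) NULL else
                do.call(rbind, lapply(r$custom_lines, unlist)))
  }))
}

#' Write a multiplet table to JSON
#' @param panel Named list of multiplet lists (as from [default_panel()]).
#' @param path Output path.
#' @export
write_multiplet_table <- function(panel, path) {
  out <- lapply(panel, function(ms) lapply(ms, function(m) {
    r <- list(center = m$center, pattern = m$pattern, J = m$J,
              fwhm = m$fwhm_hz, n_protons = m$n_protons)
    if (!is.null(m$custom_lines))
      r$custom_lines <- apply(m$custom_lines, 1, as.list)
    r
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
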