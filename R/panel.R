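#' Built-in aqueous metabolite panel
#'
#' Multiplet tables for the eight-analyte aqueous panel used throughout the
#' package (taurine, choline, creatine, lactic acid, niacinamide, L-alanine,
#' L-valine, glutamine), plus maleic acid (the quantitative reference
#' singlet) and acetic acid (the generic singlet template used for
#' interfering-signal augmentation).
#'
#' Chemical shifts and couplings are approximate literature values arranged
#' so that the panel exhibits the two deliberately overlapping pairs that
#' drive the overlap-compensation analyses: the taurine triplet and the
#' choline head-group singlet overlap near 3.1 ppm, and the glutamine and
#' alanine CH multiplets overlap near 3.7 ppm. Valine's most isolated
#' methyl doublet sits near 0.70 ppm and niacinamide contributes four
#' well-separated aromatic resonances. These are simulation fixtures, not
#' reference data.
#'
#' @param fwhm_hz Component linewidth (FWHM, Hz) used for every line.
#'   The 0.8 Hz default suits fully resolved grids; scaled-down experiment
#'   profiles pass a larger width so that lines remain resolved relative to
#'   a coarser grid.
#' @return `default_panel()`: named list of 8 multiplet lists, in panel
#'   order. `maleic_acid_multiplets()` and `acetic_acid_multiplets()`:
#'   single multiplet lists.
#' @examples
#' names(default_panel())
#' @export
default_panel <- function(fwhm_hz = 0.8) {
  mp <- function(center, pattern, J = 0, np = 1)
    multiplet(center, pattern, J = J, fwhm_hz = fwhm_hz, n_protons = np)
  list(
    taurine = list(mp(3.10, "triplet", 6.6, 2), mp(3.33, "triplet", 6.6, 2)),
    choline = list(mp(3.09, "singlet", 0, 9), mp(3.52, "doublet", 5, 2),
                   mp(4.07, "triplet", 5, 2)),
    creatine = list(mp(3.03, "singlet", 0, 3), mp(3.93, "singlet", 0, 2)),
    lactate = list(mp(1.32, "doublet", 6.9, 3), mp(4.10, "quartet", 6.9, 1)),
    niacinamide = list(mp(8.94, "singlet", 0, 1), mp(8.70, "doublet", 5, 1),
                       mp(8.25, "doublet", 8, 1), mp(7.59, "doublet", 8, 1)),
    alanine = list(mp(1.47, "doublet", 7.2, 3), mp(3.77, "quartet", 7.2, 1)),
    valine = list(mp(0.70, "doublet", 7, 3), mp(0.98, "doublet", 7, 3),
                  mp(2.26, "quartet", 7, 1), mp(3.60, "doublet", 7, 1)),
    glutamine = list(mp(3.76, "triplet", 6.3, 1), mp(2.13, "quartet", 7.6, 2),
                     mp(2.45, "quartet", 7.6, 2))
  )
}

#' @rdname default_panel
#' @export
maleic_acid_multiplets <- function(fwhm_hz = 0.8) {
  list(multiplet(6.01, "singlet", fwhm_hz = fwhm_hz, n_protons = 2))
}

#' @rdname default_panel
#' @export
acetic_acid_multiplets <- function(fwhm_hz = 0.8) {
  list(multiplet(1.91, "singlet", fwhm_hz = fwhm_hz, n_protons = 3))
}

#' Synthesize every basis spectrum of a panel on one grid
#'
#' @param grid An [nmr_grid()].
#' @param panel Named list of multiplet lists; defaults to [default_panel()].
#' @param calibration Per-proton per-mM area calibration constant.
#' @return Named list of `nmr_basis` objects in panel order.
#' @export
build_basis_set <- function(grid, panel = default_panel(), calibration = 1) {
  stats::setNames(
    lapply(names(panel), function(a)
      synthesize_basis(a, panel[[a]], grid, calibration)),
    names(panel))
}

#' All multiplet centres of a panel
#' @param panel Named list of multiplet lists.
#' @return Data frame with columns `analyte` and `ppm` (multiplet centres).
#' @export
panel_resonances <- function(panel) {
  do.call(rbind, lapply(names(panel), function(a)
    data.frame(analyte = a,
               ppm = vapply(panel[[a]], function(m) m$center, numeric(1)))))
}
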