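#' Run an expression with a temporary RNG seed
#'
#' Used internally so that every seeded operation is reproducible without
#' clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Augmentation configuration for experimental-like spectra
#'
#' Houses the magnitudes of the five augmentations that turn exact
#' noiseless mixtures into experimental-like spectra: line broadening,
#' additive Gaussian noise, rigid per-analyte chemical-shift perturbation,
#' a constant baseline offset, and insertion of randomly placed and scaled
#' interfering singlets. Noise and baseline magnitudes are expressed as
#' fractions of the (noiseless) quantitative-reference peak height.
#'
#' Per-spectrum draws are uniform within each range: the broadening in
#' `lb_range` Hz, the noise standard deviation in (0, `noise_sigma_max_frac`
#' * reference peak height), the baseline offset in (0, `baseline_max_frac`
#' * reference peak height), the shift magnitude in (0, `shift_max_ppb`)
#' with random sign per analyte, and 0 to `max_singlets` singlets with
#' concentration-equivalent scales in `singlet_conc_range`.
#'
#' @param grid [nmr_grid()] the singlet template must live on.
#' @param lb_range Line-broadening range (Hz), default 0.1 to 1.0.
#' @param noise_sigma_max_frac Maximum noise sd as a fraction of the
#'   reference peak height, default 0.013.
#' @param shift_max_ppb Maximum rigid shift per analyte (ppb), default 3.4.
#' @param baseline_max_frac Maximum baseline offset as a fraction of the
#'   reference peak height, default 0.075.
#' @param max_singlets Maximum number of inserted singlets, default 3.
#' @param singlet_template `nmr_basis` used as the generic singlet; defaults
#'   to the acetic acid singlet synthesized on `grid`.
#' @param singlet_conc_range Concentration-equivalent scale range (mM) for
#'   inserted singlets, default 1 to 50 (mirroring the analyte range).
#' @param fwhm_hz Linewidth used when synthesizing the default template.
#' @return An object of class `aug_config`.
#' @export
augmentation_config <- function(grid, lb_range = c(0.1, 1.0),
                                noise_sigma_max_frac = 0.013,
                                shift_max_ppb = 3.4,
                                baseline_max_frac = 0.075,
                                max_singlets = 3,
                                singlet_template = NULL,
                                singlet_conc_range = c(1, 50),
                                fwhm_hz = 0.8) {
  stopifnot(inherits(grid, "nmr_grid"))
  if (any(lb_range < 0) || diff(lb_range) < 0) stop("bad `lb_range`")
  if (noise_sigma_max_frac < 0 || baseline_max_frac < 0 || shift_max_ppb < 0)
    stop("augmentation magnitudes must be non-negative")
  if (max_singlets < 0) stop("`max_singlets` must be non-negative")
  if (diff(singlet_conc_range) < 0) stop("bad `singlet_conc_range`")
  if (is.null(singlet_template))
    singlet_template <- synthesize_basis("acetic_acid",
                                         acetic_acid_multiplets(fwhm_hz),
                                         grid)
  stopifnot(inherits(singlet_template, "nmr_basis"))
  if (!grids_equal(singlet_template$grid, grid))
    stop("singlet template must live on the dataset grid")
  structure(list(lb_range = lb_range,
                 noise_sigma_max_frac = noise_sigma_max_frac,
                 shift_max_ppb = shift_max_ppb,
                 baseline_max_frac = baseline_max_frac,
                 max_singlets = as.integer(max_singlets),
                 singlet_template = singlet_template,
                 singlet_conc_range = singlet_conc_range),
            class = "aug_config")
}

#' Mix basis spectra into a mixture spectrum
#'
#' Returns the exact noiseless mixture: each analyte's unit basis scaled by
#' its concentration, summed pointwise, plus the quantitative reference at
#' `ref_conc`.
#'
#' @param basis_set Named list of `nmr_basis`, one per analyte, all on the
#'   same grid, in the same order as `conc`.
#' @param conc Numeric vector of concentrations (mM), one per analyte.
#' @param ref_basis `nmr_basis` of the quantitative reference.
#' @param ref_conc Reference concentration (mM), default 13.3.
#' @return An [nmr_spectrum()].
#' @export
mix <- function(basis_set, conc, ref_basis, ref_conc = 13.3) {
  if (length(conc) != length(basis_set))
    stop("concentration vector length does not match basis set")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (ref_conc <= 0) stop("`ref_conc` must be positive")
  grid <- basis_set[[1]]$grid
  for (b in basis_set)
    if (!grids_equal(b$grid, grid)) stop("basis spectra live on different grids")
  if (!grids_equal(ref_basis$grid, grid))
    stop("reference basis lives on a different grid")
  B <- vapply(basis_set, function(b) b$unit_intensities,
              numeric(grid$n_points))
  v <- as.numeric(B %*% conc) + ref_conc * ref_basis$unit_intensities
  nmr_spectrum(grid, v)
}

## circular Lorentzian kernel with unit sum; wrapped so that discrete
## convolution preserves the total intensity exactly
.lorentz_kernel <- function(grid, lb_hz) {
  n <- grid$n_points
  h <- grid_spacing(grid)
  g <- hz_to_ppm(grid, lb_hz) / 2
  d <- (seq_len(n) - 1) * h
  d <- pmin(d, n * h - d)
  k <- (g / pi) / (d^2 + g^2)
  k / sum(k)
}

#' Apply Lorentzian line broadening
#'
#' Circular convolution with a unit-area Lorentzian kernel of FWHM `lb_hz`,
#' the frequency-domain equivalent of multiplying the FID by a decaying
#' exponential (exponential apodization). Lorentzian input lines of width
#' w0 come out with width w0 + lb. The total intensity is preserved
#' exactly; `lb_hz = 0` is the identity.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param lb_hz Added linewidth (FWHM, Hz), non-negative.
#' @return Broadened [nmr_spectrum()].
#' @export
broaden <- function(spectrum, lb_hz) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (lb_hz < 0) stop("`lb_hz` must be non-negative")
  if (lb_hz == 0) return(spectrum)
  k <- .lorentz_kernel(spectrum$grid, lb_hz)
  n <- spectrum$grid$n_points
  v <- Re(stats::fft(stats::fft(spectrum$intensities) * stats::fft(k),
                     inverse = TRUE)) / n
  nmr_spectrum(spectrum$grid, v)
}

## sub-gridpoint circular translation via a Fourier-domain phase ramp;
## npts may be fractional
.fourier_shift <- function(y, npts) {
  n <- length(y)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  ramp <- exp(-2i * pi * k * npts / n)
  if (n %% 2 == 0) ramp[n / 2 + 1] <- cos(2 * pi * (n / 2) * npts / n)
  Re(stats::fft(stats::fft(y) * ramp, inverse = TRUE)) / n
}

#' Rigidly shift a basis spectrum in chemical shift
#'
#' Translates every resonance of the basis by `delta_ppb` / 1000 ppm using
#' a Fourier-domain phase ramp, which is accurate to well below one grid
#' point and preserves the integral. Shifting by +d then -d returns the
#' original to numerical precision.
#'
#' @param basis An `nmr_basis` (or [nmr_spectrum()], shifted the same way).
#' @param delta_ppb Shift in parts per billion (0.001 ppm).
#' @return Object of the same class, shifted.
#' @export
shift_basis <- function(basis, delta_ppb) {
  if (inherits(basis, "nmr_spectrum")) {
    npts <- (delta_ppb / 1000) / grid_spacing(basis$grid)
    return(nmr_spectrum(basis$grid, .fourier_shift(basis$intensities, npts)))
  }
  stopifnot(inherits(basis, "nmr_basis"))
  npts <- (delta_ppb / 1000) / grid_spacing(basis$grid)
  out <- basis
  out$unit_intensities <- .fourier_shift(basis$unit_intensities, npts)
  out
}

#' Add i.i.d. Gaussian noise
#'
#' Adds zero-mean Gaussian noise of standard deviation `sigma` to every
#' point. Uses the session RNG; seed the caller (or pass `seed`) for
#' reproducibility.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param sigma Noise standard deviation (intensity units), non-negative.
#' @param seed Optional integer seed applied locally.
#' @return Noisy [nmr_spectrum()].
#' @export
add_noise <- function(spectrum, sigma, seed = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(spectrum)
  noise <- if (is.null(seed)) stats::rnorm(spectrum$grid$n_points, 0, sigma)
           else with_seed(seed, stats::rnorm(spectrum$grid$n_points, 0, sigma))
  nmr_spectrum(spectrum$grid, spectrum$intensities + noise)
}

#' Add a constant baseline offset
#' @param spectrum An [nmr_spectrum()].
#' @param offset Intensity added to every point.
#' @return Offset [nmr_spectrum()].
#' @export
add_baseline_offset <- function(spectrum, offset) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  nmr_spectrum(spectrum$grid, spectrum$intensities + offset)
}

#' Insert randomly placed interfering singlets
#'
#' Draws k uniform in 0..`max_singlets`; for each singlet draws a chemical
#' shift uniform in the grid window and a concentration-equivalent scale
#' uniform in `singlet_conc_range`, then inserts the shifted, scaled
#' singlet template. The returned records allow downstream audits of the
#' attribution the model assigns to these non-analyte signals.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param config An [augmentation_config()] (provides the template, count
#'   and scale range).
#' @param n_singlets Optional fixed singlet count overriding the random
#'   draw.
#' @param near Optional vector of resonance positions (ppm). When given,
#'   each singlet is placed adjacent to a randomly chosen resonance — at
#'   an offset of 7 to 11 template linewidths, and at least 6.5
#'   linewidths from every position in `near` — so that the singlet is
#'   close enough to interfere but a 5-linewidth audit window around it
#'   stays free of analyte peaks. When `NULL`, placement is uniform over
#'   the window.
#' @return List with elements `spectrum` and `records` (data frame with
#'   columns `ppm` and `conc`, zero rows when no singlet was inserted).
#' @export
add_singlets <- function(spectrum, config, n_singlets = NULL, near = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(config, "aug_config"))
  tmpl <- config$singlet_template
  if (!grids_equal(tmpl$grid, spectrum$grid))
    stop("singlet template grid does not match the spectrum")
  k <- if (is.null(n_singlets)) sample(0:config$max_singlets, 1)
       else as.integer(n_singlets)
  recs <- data.frame(ppm = numeric(0), conc = numeric(0))
  if (k == 0) return(list(spectrum = spectrum, records = recs))
  g <- spectrum$grid
  tmpl_center <- ppm_axis(g)[which.max(tmpl$unit_intensities)]
  fwhm_ppm <- .template_fwhm_ppm(tmpl)
  v <- spectrum$intensities
  hw <- 5 * fwhm_ppm
  for (s in seq_len(k)) {
    ppm_s <- if (is.null(near)) {
      stats::runif(1, g$ppm_min + 0.1, g$ppm_max - 0.1)
    } else {
      p <- NA
      for (try in 1:200) {
        ctr <- near[sample.int(length(near), 1)]
        p <- ctr + sample(c(-1, 1), 1) *
          stats::runif(1, hw + 2 * fwhm_ppm, hw + 6 * fwhm_ppm)
        if (p > g$ppm_min + 0.2 && p < g$ppm_max - 0.2 &&
            min(abs(p - near)) > hw + 1.5 * fwhm_ppm) break
        p <- NA
      }
      if (is.na(p)) stop("could not place a singlet clear of the resonances")
      p
    }
    conc_s <- stats::runif(1, config$singlet_conc_range[1],
                           config$singlet_conc_range[2])
    moved <- shift_basis(tmpl, (ppm_s - tmpl_center) * 1000)
    v <- v + conc_s * moved$unit_intensities
    recs <- rbind(recs, data.frame(ppm = ppm_s, conc = conc_s))
  }
  list(spectrum = nmr_spectrum(g, v), records = recs)
}

## FWHM (ppm) of the singlet template, measured at half maximum
.template_fwhm_ppm <- function(tmpl) {
  y <- tmpl$unit_intensities
  above <- y >= max(y) / 2
  sum(above) * grid_spacing(tmpl$grid)
}

#' Sample a random concentration vector
#'
#' Each analyte is independently left out (set to exactly 0) with
#' probability `leave_out_prob`, otherwise drawn uniformly from
#' `[low, high]` mM.
#'
#' @param panel_names Character vector of analyte names (sets the order).
#' @param low,high Concentration range (mM), default 1 to 50.
#' @param leave_out_prob Per-analyte leave-out probability in `[0, 1]`.
#' @return Named numeric vector of concentrations (mM).
#' @export
sample_concentrations <- function(panel_names, low = 1, high = 50,
                                  leave_out_prob = 0) {
  if (leave_out_prob < 0 || leave_out_prob > 1)
    stop("`leave_out_prob` must be in [0, 1]")
  if (low > high) stop("`low` must not exceed `high`")
  n <- length(panel_names)
  v <- stats::runif(n, low, high)
  v[stats::runif(n) < leave_out_prob] <- 0
  stats::setNames(v, panel_names)
}
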