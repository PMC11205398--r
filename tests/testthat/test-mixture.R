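grid_mix <- nmr_grid(0.48, 9.52, 2048, 400)
basis_mix <- build_basis_set(grid_mix, default_panel(fwhm_hz = 6))
ref_mix <- synthesize_basis("maleic_acid", maleic_acid_multiplets(6),
                            grid_mix)

test_that("mixing is linear and anchors the reference at its fixed concentration", {
  zeros <- setNames(rep(0, 8), names(basis_mix))
  sp0 <- mix(basis_mix, zeros, ref_mix)
  expect_equal(sp0$intensities, 13.3 * ref_mix$unit_intensities)

  c1 <- setNames(c(2, 0, 0, 0, 0, 0, 0, 0), names(basis_mix))
  c2 <- setNames(c(0, 3, 0, 0, 0, 0, 0, 0), names(basis_mix))
  s1 <- mix(basis_mix, c1, ref_mix)
  s2 <- mix(basis_mix, c2, ref_mix)
  s12 <- mix(basis_mix, c1 + c2, ref_mix)
  ## mixture linearity with the reference term counted once
  expect_equal(s12$intensities,
               s1$intensities + s2$intensities -
                 13.3 * ref_mix$unit_intensities,
               tolerance = 1e-12)

  ## reference peak height is ref_conc x unit height on top of analyte level
  i_ref <- which.max(ref_mix$unit_intensities)
  analyte_part <- mix(basis_mix, setNames(rep(25, 8), names(basis_mix)),
                      ref_mix, ref_conc = 1e-12)
  sp25 <- mix(basis_mix, setNames(rep(25, 8), names(basis_mix)), ref_mix)
  expect_equal(sp25$intensities[i_ref] - analyte_part$intensities[i_ref],
               13.3 * ref_mix$unit_intensities[i_ref], tolerance = 1e-6)

  expect_error(mix(basis_mix, rep(1, 3), ref_mix), "length")
})

test_that("line broadening preserves the integral and adds Lorentzian widths", {
  g <- fine_grid()
  sp <- nmr_spectrum(g, lorentzian_line(3, 2, 5, g))
  expect_equal(broaden(sp, 0)$intensities, sp$intensities)
  br <- broaden(sp, 1.5)
  expect_lt(abs(spectrum_integral(br) - spectrum_integral(sp)) /
              spectrum_integral(sp), 1e-4)

  ## measured FWHM of a 2 Hz line broadened by 1.5 Hz is 3.5 Hz
  ax <- ppm_axis(g)
  measure_fwhm <- function(y) {
    above <- y >= max(y) / 2
    (diff(range(ax[above])) + grid_spacing(g)) * g$freq_mhz
  }
  expect_equal(measure_fwhm(br$intensities), 3.5, tolerance = 0.05)
  expect_error(broaden(sp, -1), "non-negative")
})

test_that("sub-gridpoint shifts are exact at integer spacings and invertible", {
  ## linewidth well above the grid spacing (band-limited content) and a
  ## window-centred line (negligible edge step): Fourier shifts of
  ## unresolved spikes or strongly asymmetric tails lose precision at the
  ## Nyquist bin
  g <- nmr_grid(0.48, 9.52, 1024, 400)
  b <- synthesize_basis("t", list(multiplet(5, "singlet", fwhm_hz = 64,
                                            n_protons = 2)), g)
  expect_equal(shift_basis(b, 0)$unit_intensities, b$unit_intensities)

  ## shifting by exactly one grid spacing equals an integer roll
  d_ppb <- grid_spacing(g) * 1000
  sh <- shift_basis(b, d_ppb)
  rolled <- c(b$unit_intensities[g$n_points],
              b$unit_intensities[-g$n_points])
  expect_lt(max(abs(sh$unit_intensities - rolled)), 1e-9)

  ## +d then -d is the identity
  back <- shift_basis(shift_basis(b, 1.7), -1.7)
  expect_lt(max(abs(back$unit_intensities - b$unit_intensities)), 1e-9)

  ## total intensity preserved exactly (the k = 0 bin is untouched)
  expect_lt(abs(sum(sh$unit_intensities) - sum(b$unit_intensities)) *
              grid_spacing(g), 1e-9)
})

test_that("noise injection recovers sigma and is seed-reproducible", {
  g <- nmr_grid(0, 10, 39500, 400)
  sp <- nmr_spectrum(g, rep(1, g$n_points))
  expect_equal(add_noise(sp, 0)$intensities, sp$intensities)
  noisy <- add_noise(sp, 0.37, seed = 99)
  expect_equal(sd(noisy$intensities - sp$intensities), 0.37,
               tolerance = 0.03)
  expect_equal(add_noise(sp, 0.37, seed = 99)$intensities,
               noisy$intensities)
  expect_error(add_noise(sp, -1), "non-negative")
})

test_that("baseline offsets shift the mean and cancel exactly", {
  g <- nmr_grid(0, 10, 256, 400)
  sp <- nmr_spectrum(g, rnorm(256))
  up <- add_baseline_offset(sp, 0.4)
  expect_equal(mean(up$intensities) - mean(sp$intensities), 0.4)
  expect_equal(add_baseline_offset(up, -0.4)$intensities, sp$intensities)
})

test_that("singlet insertion is bookkept: counts, local areas, uniform draw", {
  g <- nmr_grid(0.48, 9.52, 2048, 400)
  aug <- augmentation_config(g, fwhm_hz = 6)
  base <- nmr_spectrum(g, rep(0, g$n_points))

  none <- add_singlets(base, aug, n_singlets = 0)
  expect_equal(none$spectrum$intensities, base$intensities)
  expect_equal(nrow(none$records), 0)

  tmpl_area <- spectrum_integral(aug$singlet_template$unit_intensities,
                                 grid = g)
  set.seed(5)
  out <- add_singlets(base, aug, n_singlets = 3)
  expect_equal(nrow(out$records), 3)
  for (i in seq_len(3)) {
    w <- abs(ppm_axis(g) - out$records$ppm[i]) < 0.5
    ## local integral around an isolated record ~= conc x template area;
    ## allow for overlap with the other inserted singlets' tails
    others <- sum(out$records$conc[-i]) * tmpl_area * 0.2
    loc <- sum(out$spectrum$intensities[w]) * grid_spacing(g)
    expect_lt(abs(loc - out$records$conc[i] * tmpl_area),
              0.02 * out$records$conc[i] * tmpl_area + others)
  }

  ## the random count is uniform on 0..3: mean 1.5 over many draws
  set.seed(11)
  ks <- replicate(4000, nrow(add_singlets(base, aug)$records))
  expect_equal(mean(ks), 1.5, tolerance = 0.05 / 1.5)
})

test_that("concentration sampling hits the range and the leave-out rate", {
  panel_names <- names(default_panel())
  set.seed(3)
  v <- sample_concentrations(panel_names, leave_out_prob = 0)
  expect_true(all(v >= 1 & v <= 50))
  expect_equal(sample_concentrations(panel_names, leave_out_prob = 1),
               setNames(rep(0, 8), panel_names))
  draws <- replicate(10000,
    sample_concentrations(panel_names, leave_out_prob = 0.5) == 0)
  zero_frac <- rowMeans(draws)
  expect_true(all(zero_frac >= 0.48 & zero_frac <= 0.52))
})

test_that("dataset generation is deterministic, normalized, and correctly split", {
  g <- nmr_grid(0.48, 9.52, 256, 400)
  sizes <- list(n_all = 120, n_dropout = 120, n_validation = 40)
  ds <- generate_dataset("simulated", sizes, g, seed = 7, fwhm_hz = 10)
  ds2 <- generate_dataset("simulated", sizes, g, seed = 7, fwhm_hz = 10)
  expect_identical(ds$spectra, ds2$spectra)
  expect_identical(ds$concentrations, ds2$concentrations)
  expect_identical(ds$split, ds2$split)

  expect_equal(max(ds$spectra[ds$split != "validation", ]), 1.0)
  expect_equal(sum(ds$split == "train"), 192)
  expect_equal(sum(ds$split == "test"), 48)
  expect_equal(sum(ds$split == "validation"), 40)

  ## the simulated recipe emits exact noiseless mixtures
  bs <- build_basis_set(g, default_panel(10))
  rb <- synthesize_basis("maleic_acid", maleic_acid_multiplets(10), g)
  i <- 17
  expected <- mix(bs, ds$concentrations[i, ], rb)$intensities /
    ds$norm_constant
  expect_equal(ds$spectra[i, ], expected, tolerance = 1e-12)

  ## dropout rows have exact zeros; all-present rows never do
  expect_true(any(ds$concentrations[121:240, ] == 0))
  expect_true(all(ds$concentrations[1:120, ] > 0))
  expect_true(all(ds$concentrations[ds$split == "validation", ] > 0))
})

test_that("experimental-like datasets differ from clean mixtures but stay labeled", {
  g <- nmr_grid(0.48, 9.52, 256, 400)
  aug <- augmentation_config(g, fwhm_hz = 10)
  sizes <- list(n_all = 30, n_dropout = 30, n_validation = 10)
  ds <- generate_dataset("experimental_like", sizes, g, aug = aug,
                         seed = 7, fwhm_hz = 10)
  expect_equal(dim(ds$spectra), c(70, 256))
  expect_equal(max(ds$spectra[ds$split != "validation", ]), 1.0)
  expect_length(ds$singlet_records, 70)
  expect_error(generate_dataset("experimental_like", sizes, g, seed = 1),
               "augmentation")
})

test_that("named fixtures reproduce their compositions", {
  g <- nmr_grid(0.48, 9.52, 512, 400)
  fx <- make_fixture("equimolar_25", g, fwhm_hz = 8)
  expect_equal(unname(fx$conc), rep(25, 8))
  expect_equal(nrow(fx$records), 0)

  fx1 <- make_fixture("equimolar_1", g, fwhm_hz = 8)
  expect_equal(unname(fx1$conc), rep(1, 8))

  six <- make_fixture("six_analytes_25_noisy", g, fwhm_hz = 8)
  expect_equal(unname(six$conc[c("glutamine", "taurine")]), c(0, 0))
  expect_equal(sum(six$conc > 0), 6)

  two <- make_fixture("plus_two_singlets", g, seed = 3, fwhm_hz = 8)
  expect_equal(nrow(two$records), 2)
  expect_equal(unname(two$conc), rep(25, 8))
  ## same seed reproduces the fixture exactly
  two_b <- make_fixture("plus_two_singlets", g, seed = 3, fwhm_hz = 8)
  expect_identical(two$spectrum$intensities, two_b$spectrum$intensities)
})

test_that("datasets round-trip through their on-disk container", {
  g <- nmr_grid(0.48, 9.52, 128, 400)
  ds <- generate_dataset("simulated",
                         list(n_all = 20, n_dropout = 20, n_validation = 5),
                         g, seed = 2, fwhm_hz = 12)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rt <- read_dataset(dir)
  expect_equal(rt$spectra, ds$spectra)
  expect_equal(rt$norm_constant, ds$norm_constant)
  expect_equal(as.character(rt$split), as.character(ds$split))
})
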