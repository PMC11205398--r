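test_that("grid construction gives the documented spacings and rejects bad input", {
  g <- nmr_grid(0.48, 9.52, 39500, 400)
  expect_equal(grid_spacing(g), 9.04 / 39499, tolerance = 1e-12)
  expect_equal(ppm_axis(nmr_grid(0, 1, 2, 400)), c(0, 1))
  expect_equal(grid_spacing(nmr_grid(0, 10, 11, 400)), 1.0)
  expect_error(nmr_grid(5, 2, 100, 400), "less than")
  expect_error(nmr_grid(0, 1, 1, 400), ">= 2")
})

test_that("ppm/index round trip stays within one grid spacing", {
  g <- nmr_grid(0.48, 9.52, 4096, 400)
  ax <- ppm_axis(g)
  probes <- runif(50, g$ppm_min, g$ppm_max)
  idx <- ppm_to_index(g, probes)
  expect_true(all(abs(ax[idx] - probes) <= grid_spacing(g)))
})

test_that("lorentzian lines have unit area, the stated width, and scale linearly", {
  g <- fine_grid()
  y <- lorentzian_line(3, 0.8, 1, g)
  expect_lt(abs(spectrum_integral(y, grid = g) - 1), 0.02)

  ## FWHM measured numerically: 0.8 Hz at 400 MHz is 0.002 ppm
  ax <- ppm_axis(g)
  above <- y >= max(y) / 2
  width <- diff(range(ax[above])) + grid_spacing(g)
  expect_equal(width, 0.002, tolerance = 0.05)

  y2 <- lorentzian_line(3, 0.8, 2, g)
  expect_equal(y2, 2 * y, tolerance = 1e-12)

  expect_error(lorentzian_line(10, 0.8, 1, g), "outside")
  expect_error(lorentzian_line(3, 0, 1, g), "positive")
})

test_that("basis synthesis conserves area and is additive over multiplet lists", {
  g <- fine_grid()
  m1 <- multiplet(2.8, "singlet", n_protons = 2)
  m2 <- multiplet(3.4, "doublet", J = 7, n_protons = 3)
  b1 <- synthesize_basis("a", list(m1), g)
  b2 <- synthesize_basis("b", list(m2), g)
  b12 <- synthesize_basis("ab", list(m1, m2), g)
  expect_equal(b12$unit_intensities,
               b1$unit_intensities + b2$unit_intensities)
  expect_equal(b12$n_protons, 5)
  ## area = calibration x proton count, up to truncated Lorentzian tails
  expect_lt(abs(spectrum_integral(b12$unit_intensities, grid = g) - 5) / 5,
            0.02)
  ## calibration scales the area
  b1c <- synthesize_basis("a", list(m1), g, calibration = 2.5)
  expect_equal(b1c$unit_intensities, 2.5 * b1$unit_intensities)
})

test_that("a J = 7 Hz doublet at 400 MHz shows two maxima 0.0175 ppm apart", {
  g <- fine_grid()
  b <- synthesize_basis("d", list(multiplet(3, "doublet", J = 7,
                                            n_protons = 1)), g)
  y <- b$unit_intensities
  ax <- ppm_axis(g)
  loc_max <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(loc_max, 2)
  expect_equal(diff(ax[loc_max]), 7 / 400, tolerance = 0.02)
})

test_that("standard multiplet patterns follow the binomial weight rows", {
  lines <- multiplet_lines(multiplet(1, "quartet", J = 8), 400)
  expect_equal(lines$weight, c(1, 3, 3, 1) / 8)
  expect_equal(diff(lines$ppm), rep(8 / 400, 3), tolerance = 1e-12)
  tri <- multiplet_lines(multiplet(1, "triplet", J = 6), 400)
  expect_equal(tri$weight, c(1, 2, 1) / 4)
})

test_that("the default panel places the documented overlaps and isolated peaks", {
  res <- panel_resonances(default_panel())
  near <- function(analyte, target, tol = 0.12)
    any(abs(res$ppm[res$analyte == analyte] - target) < tol)
  ## the two deliberately overlapping pairs
  expect_true(near("alanine", 3.77) && near("glutamine", 3.77))
  expect_true(near("taurine", 3.10) && near("choline", 3.10))
  ## valine's isolated methyl and the reference singlet
  expect_true(near("valine", 0.70))
  expect_length(maleic_acid_multiplets(), 1)
  expect_equal(maleic_acid_multiplets()[[1]]$pattern, "singlet")
  ## niacinamide has four aromatic multiplets
  expect_length(default_panel()$niacinamide, 4)

  ## the overlap is real: >1% support regions of each pair intersect
  g <- nmr_grid(0.48, 9.52, 8192, 400)
  bs <- build_basis_set(g)
  rois <- default_analyte_rois(bs)
  intersects <- function(a, b)
    length(nmrxai:::.nonoverlapping_rois(rois, a, b)) < length(rois[[b]])
  expect_true(intersects("alanine", "glutamine"))
  expect_true(intersects("taurine", "choline"))
})

test_that("multiplet tables round-trip through JSON", {
  panel <- default_panel(fwhm_hz = 1.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_multiplet_table(panel, path)
  rt <- read_multiplet_table(path)
  expect_named(rt, names(panel))
  g <- nmr_grid(0.48, 9.52, 2048, 400)
  for (a in c("creatine", "valine")) {
    b1 <- synthesize_basis(a, panel[[a]], g)
    b2 <- synthesize_basis(a, rt[[a]], g)
    expect_equal(b2$unit_intensities, b1$unit_intensities)
  }
})

test_that("two-column text spectra round-trip and tolerate descending axes", {
  g <- nmr_grid(1, 5, 513, 400)
  sp <- nmr_spectrum(g, lorentzian_line(3, 2, 5, g))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path, "two_column_text")
  rt <- read_spectrum(path, "two_column_text")
  expect_equal(rt$intensities, sp$intensities, tolerance = 1e-12)
  expect_equal(ppm_axis(rt$grid), ppm_axis(g), tolerance = 1e-12)

  ## same data stored descending reads back identically
  desc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(sprintf("%.17g", rev(ppm_axis(g))),
                   sprintf("%.17g", rev(sp$intensities)), sep = "\t"), desc)
  rt2 <- read_spectrum(desc, "two_column_text")
  expect_equal(rt2$intensities, sp$intensities, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1.0\t2.0", "not-a-number"), bad)
  expect_error(read_spectrum(bad, "two_column_text"), "line 2")
})

test_that("JCAMP-DX output is re-readable and resampling preserves constants", {
  g <- nmr_grid(1, 5, 257, 400)
  sp <- nmr_spectrum(g, lorentzian_line(3, 2, 5, g) + 0.5)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(sp, path, "jcamp_dx")
  rt <- read_spectrum(path, "jcamp_dx")
  expect_equal(rt$intensities, sp$intensities, tolerance = 1e-9)
  expect_equal(rt$grid$freq_mhz, 400)

  ## format sniffing
  rt_auto <- read_spectrum(path)
  expect_equal(rt_auto$intensities, sp$intensities, tolerance = 1e-9)

  ## constant spectrum resampled onto a finer grid stays constant
  flat <- nmr_spectrum(g, rep(2.5, g$n_points))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(flat, p2, "two_column_text")
  finer <- nmr_grid(1, 5, 1025, 400)
  rs <- read_spectrum(p2, grid = finer)
  expect_equal(rs$intensities, rep(2.5, 1025))

  ## smooth (grid-resolved) spectrum: integral preserved within 0.5%
  smooth <- nmr_spectrum(g, lorentzian_line(3, 80, 5, g))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(smooth, p3, "two_column_text")
  rs2 <- read_spectrum(p3, grid = nmr_grid(1, 5, 199, 400))
  expect_lt(abs(spectrum_integral(rs2) - spectrum_integral(smooth)) /
              spectrum_integral(smooth), 0.005)
})
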