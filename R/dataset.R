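#' Generate a labeled training/testing/validation dataset
#'
#' Implements the two dataset recipes used for model training. Both draw
#' `n_all` spectra with every analyte present (concentrations uniform in
#' `conc_range` mM) and `n_dropout` spectra in which each analyte is
#' independently left out with probability `leave_out_prob`; the pooled
#' spectra are split 80:20 into train and test at random. A further
#' `n_validation` all-analytes-present spectra form the validation split.
#' The quantitative reference is present at `ref_conc` mM in every
#' spectrum.
#'
#' The `simulated` recipe emits exact noiseless mixtures. The
#' `experimental_like` recipe applies, per spectrum and in this order:
#' rigid per-analyte chemical-shift perturbation, mixing, line broadening,
#' insertion of random interfering singlets, a constant baseline offset,
#' and additive Gaussian noise, with per-spectrum magnitudes drawn
#' uniformly within the [augmentation_config()] ranges.
#'
#' Finally all spectra are divided by the maximum intensity over the
#' train and test splits (`norm_constant`), so the train/test maximum is
#' exactly 1.
#'
#' @param recipe `"simulated"` or `"experimental_like"`.
#' @param sizes List with `n_all`, `n_dropout`, `n_validation`.
#' @param grid An [nmr_grid()].
#' @param panel Named list of multiplet lists; default [default_panel()].
#' @param aug An [augmentation_config()]; required for
#'   `experimental_like`, ignored otherwise.
#' @param seed Integer seed; identical seed and configuration reproduce
#'   the dataset bit for bit.
#' @param ref_conc Reference concentration (mM), default 13.3.
#' @param conc_range Analyte concentration range (mM), default `c(1, 50)`.
#' @param leave_out_prob Leave-out probability for the dropout half,
#'   default 0.5.
#' @param calibration Per-proton per-mM area calibration.
#' @param fwhm_hz Panel linewidth passed to [default_panel()] when `panel`
#'   is not supplied explicitly.
#' @return An object of class `nmr_dataset`: list with `spectra`
#'   (n_samples x n_points, normalized), `concentrations` (n_samples x
#'   n_analytes, mM), `split` (factor train/test/validation),
#'   `norm_constant`, `seed`, `singlet_records`, `ref_peak_height` (raw
#'   units, noiseless), and `provenance`.
#' @export
generate_dataset <- function(recipe = c("simulated", "experimental_like"),
                             sizes = list(n_all = 10000, n_dropout = 10000,
                                          n_validation = 5000),
                             grid, panel = NULL, aug = NULL, seed = 1,
                             ref_conc = 13.3, conc_range = c(1, 50),
                             leave_out_prob = 0.5, calibration = 1,
                             fwhm_hz = 0.8) {
  recipe <- match.arg(recipe)
  stopifnot(inherits(grid, "nmr_grid"))
  if (any(unlist(sizes) <= 0)) stop("all sizes must be positive")
  if (recipe == "experimental_like" && is.null(aug))
    stop("`experimental_like` recipe requires an augmentation config")
  if (is.null(panel)) panel <- default_panel(fwhm_hz)
  basis_set <- build_basis_set(grid, panel, calibration)
  ref_basis <- synthesize_basis("maleic_acid", maleic_acid_multiplets(fwhm_hz),
                                grid, calibration)
  ref_peak <- ref_conc * max(ref_basis$unit_intensities)
  na <- length(basis_set)
  n_pool <- sizes$n_all + sizes$n_dropout
  n_total <- n_pool + sizes$n_validation

  with_seed(seed, {
    C <- matrix(0, n_total, na,
                dimnames = list(NULL, names(basis_set)))
    for (i in seq_len(n_total)) {
      p <- if (i > sizes$n_all && i <= n_pool) leave_out_prob else 0
      C[i, ] <- sample_concentrations(names(basis_set), conc_range[1],
                                      conc_range[2], p)
    }
    B <- vapply(basis_set, function(b) b$unit_intensities,
                numeric(grid$n_points))
    records <- vector("list", n_total)
    if (recipe == "simulated") {
      X <- tcrossprod(C, B) +
        matrix(ref_conc * ref_basis$unit_intensities, n_total,
               grid$n_points, byrow = TRUE)
      for (i in seq_len(n_total)) records[[i]] <-
          data.frame(ppm = numeric(0), conc = numeric(0))
    } else {
      X <- matrix(0, n_total, grid$n_points)
      sig_max <- aug$noise_sigma_max_frac * ref_peak
      base_max <- aug$baseline_max_frac * ref_peak
      for (i in seq_len(n_total)) {
        shifted <- matrix(0, grid$n_points, na)
        for (j in seq_len(na)) {
          d <- sample(c(-1, 1), 1) * stats::runif(1, 0, aug$shift_max_ppb)
          shifted[, j] <- if (C[i, j] > 0)
            shift_basis(basis_set[[j]], d)$unit_intensities
          else B[, j]
        }
        v <- as.numeric(shifted %*% C[i, ]) +
          ref_conc * ref_basis$unit_intensities
        sp <- broaden(nmr_spectrum(grid, v),
                      stats::runif(1, aug$lb_range[1], aug$lb_range[2]))
        sg <- add_singlets(sp, aug)
        sp <- add_baseline_offset(sg$spectrum,
                                  stats::runif(1, 0, base_max))
        sp <- add_noise(sp, stats::runif(1, 0, sig_max))
        X[i, ] <- sp$intensities
        records[[i]] <- sg$records
      }
    }
    pool_split <- rep("test", n_pool)
    pool_split[sample.int(n_pool, floor(0.8 * n_pool))] <- "train"
    split <- factor(c(pool_split, rep("validation", sizes$n_validation)),
                    levels = c("train", "test", "validation"))
  })

  norm_constant <- max(X[split != "validation", ])
  X <- X / norm_constant
  structure(list(spectra = X, concentrations = C, split = split,
                 norm_constant = norm_constant, seed = seed,
                 singlet_records = records,
                 ref_peak_height = ref_peak,
                 grid = grid,
                 provenance = list(recipe = recipe, sizes = sizes,
                                   ref_conc = ref_conc,
                                   conc_range = conc_range,
                                   leave_out_prob = leave_out_prob,
                                   calibration = calibration,
                                   fwhm_hz = fwhm_hz,
                                   panel = names(basis_set),
                                   augmented = !is.null(aug) &&
                                     recipe == "experimental_like")),
            class = "nmr_dataset")
}

#' @export
print.nmr_dataset <- function(x, ...) {
  cat(sprintf(
    "<nmr_dataset> %s recipe: %d spectra x %d points (%d train / %d test / %d validation)\n",
    x$provenance$recipe, nrow(x$spectra), ncol(x$spectra),
    sum(x$split == "train"), sum(x$split == "test"),
    sum(x$split == "validation")))
  invisible(x)
}

#' Save / load a dataset
#'
#' The container is a directory holding the arrays (`arrays.rds`) and a
#' JSON manifest with the panel, grid, seed and configuration snapshot.
#'
#' @param dataset An `nmr_dataset`.
#' @param dir Directory to create/read.
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: the dataset.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset[c("spectra", "concentrations", "split", "singlet_records")],
          file.path(dir, "arrays.rds"))
  manifest <- c(dataset$provenance,
                list(norm_constant = dataset$norm_constant,
                     seed = dataset$seed,
                     ref_peak_height = dataset$ref_peak_height,
                     grid = unclass(dataset$grid)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  arrays <- readRDS(file.path(dir, "arrays.rds"))
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  grid <- nmr_grid(m$grid$ppm_min, m$grid$ppm_max, m$grid$n_points,
                   m$grid$freq_mhz)
  structure(c(arrays,
              list(norm_constant = m$norm_constant, seed = m$seed,
                   ref_peak_height = m$ref_peak_height, grid = grid,
                   provenance = m[setdiff(names(m),
                                          c("norm_constant", "seed",
                                            "ref_peak_height", "grid"))])),
            class = "nmr_dataset")
}

#' Named validation fixtures
#'
#' Reproduces the named spectra used to probe trained models:
#' equimolar mixtures of all eight analytes at 25, 5 and 1 mM
#' (`equimolar_25`, `equimolar_5`, `equimolar_1`), the 25 mM mixture plus
#' two interfering singlets placed near randomly chosen analyte resonances
#' (`plus_two_singlets`, and `plus_two_singlets_noisy` with noise at the
#' mean training magnitude), and a six-analyte 25 mM mixture leaving out
#' glutamine and taurine plus noise (`six_analytes_25_noisy`).
#'
#' Noisy fixtures use sigma equal to half the maximum training noise sd
#' (the mean of the uniform per-spectrum draw).
#'
#' @param name Fixture name (see above).
#' @param grid An [nmr_grid()].
#' @param panel Named list of multiplet lists; default [default_panel()].
#' @param aug Optional [augmentation_config()]; required for fixtures that
#'   add singlets or noise.
#' @param seed Integer seed for the random singlet placement and noise.
#' @param ref_conc Reference concentration (mM).
#' @param calibration Per-proton per-mM area calibration.
#' @param fwhm_hz Panel linewidth when `panel` is not supplied.
#' @return List with `spectrum` (raw, unnormalized [nmr_spectrum()]),
#'   `conc` (named mM vector with exact zeros for absent analytes) and
#'   `records` (singlet records data frame).
#' @export
make_fixture <- function(name = c("equimolar_25", "equimolar_5", "equimolar_1",
                                  "plus_two_singlets",
                                  "plus_two_singlets_noisy",
                                  "six_analytes_25_noisy"),
                         grid, panel = NULL, aug = NULL, seed = 1,
                         ref_conc = 13.3, calibration = 1, fwhm_hz = 0.8) {
  name <- match.arg(name)
  stopifnot(inherits(grid, "nmr_grid"))
  if (is.null(panel)) panel <- default_panel(fwhm_hz)
  basis_set <- build_basis_set(grid, panel, calibration)
  ref_basis <- synthesize_basis("maleic_acid", maleic_acid_multiplets(fwhm_hz),
                                grid, calibration)
  ref_peak <- ref_conc * max(ref_basis$unit_intensities)
  need_aug <- name %in% c("plus_two_singlets", "plus_two_singlets_noisy",
                          "six_analytes_25_noisy")
  if (need_aug && is.null(aug))
    aug <- augmentation_config(grid, fwhm_hz = fwhm_hz)
  sigma_mean <- if (need_aug) 0.5 * aug$noise_sigma_max_frac * ref_peak else 0

  conc <- stats::setNames(rep(25, length(basis_set)), names(basis_set))
  if (name == "equimolar_5") conc[] <- 5
  if (name == "equimolar_1") conc[] <- 1
  if (name == "six_analytes_25_noisy")
    conc[c("glutamine", "taurine")] <- 0

  with_seed(seed, {
    sp <- mix(basis_set, conc, ref_basis, ref_conc)
    records <- data.frame(ppm = numeric(0), conc = numeric(0))
    if (name %in% c("plus_two_singlets", "plus_two_singlets_noisy")) {
      res <- panel_resonances(panel)
      sg <- add_singlets(sp, aug, n_singlets = 2, near = res$ppm)
      sp <- sg$spectrum
      records <- sg$records
    }
    if (name %in% c("plus_two_singlets_noisy", "six_analytes_25_noisy"))
      sp <- add_noise(sp, sigma_mean)
  })
  list(spectrum = sp, conc = conc, records = records)
}
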