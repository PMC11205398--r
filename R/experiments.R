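#' Experiment configuration profiles
#'
#' Bundles everything the end-to-end studies need: the grid, panel,
#' augmentation config, model and training configurations, and the
#' integration config, at one of three scales.
#'
#' The `ci` and `desk` profiles are scaled-down study conditions chosen to
#' run on a single CPU: a coarser grid over the same 0.48-9.52 ppm window,
#' a narrower hidden layer, and fewer spectra and epochs. On these grids
#' the panel linewidth is widened to two grid spacings so every line
#' remains resolved relative to the grid, preserving the
#' resolved-lineshape character of the full-resolution setting. The `full`
#' profile reproduces the reference sizes (39,500-point grid, 200 hidden
#' nodes, 10,000 + 10,000 + 5,000 spectra) and is not intended for
#' routine runs.
#'
#' @param scale `"ci"`, `"desk"` or `"full"`.
#' @param seed Master seed; dataset, model and fixture seeds derive from
#'   it.
#' @param out_dir Optional output directory for reports.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("desk", "ci", "full"), seed = 1,
                              out_dir = NULL) {
  scale <- match.arg(scale)
  p <- switch(scale,
    ci   = list(n_points = 768, hidden = 64, n_all = 600, n_dropout = 600,
                n_validation = 200, epochs_sim = 800, epochs_exp = 800,
                lr = 3e-3),
    desk = list(n_points = 1024, hidden = 128, n_all = 3000,
                n_dropout = 3000, n_validation = 500, epochs_sim = 1200,
                epochs_exp = 2000, lr = 3e-3),
    full = list(n_points = 39500, hidden = 200, n_all = 10000,
                n_dropout = 10000, n_validation = 5000, epochs_sim = 5000,
                epochs_exp = 100000, lr = 1e-3))
  grid <- nmr_grid(0.48, 9.52, p$n_points, 400)
  fwhm_hz <- if (scale == "full") 0.8
             else 2 * grid_spacing(grid) * grid$freq_mhz
  structure(list(scale = scale, seed = as.integer(seed), grid = grid,
                 fwhm_hz = fwhm_hz,
                 panel = default_panel(fwhm_hz),
                 sizes = p[c("n_all", "n_dropout", "n_validation")],
                 hidden = p$hidden, lr = p$lr,
                 roi_threshold = switch(scale, full = 0.01, desk = 0.03,
                                        ci = 0.05),
                 epochs_sim = p$epochs_sim, epochs_exp = p$epochs_exp,
                 ig = ig_config(m_steps = 128,
                                completeness_tolerance = 1e-4,
                                m_max = 4096),
                 out_dir = out_dir),
            class = "experiment_config")
}

## shared plumbing: generate a dataset and train a model under a profile
.study_dataset <- function(config, recipe) {
  aug <- if (recipe == "experimental_like")
    augmentation_config(config$grid, fwhm_hz = config$fwhm_hz) else NULL
  generate_dataset(recipe, sizes = config$sizes, grid = config$grid,
                   panel = config$panel, aug = aug,
                   seed = config$seed + if (recipe == "simulated") 0L else 1L,
                   fwhm_hz = config$fwhm_hz)
}

.study_model <- function(config, dataset, recipe, verbose = 0) {
  spec <- model_spec(n_in = config$grid$n_points, hidden = config$hidden,
                     n_out = length(config$panel), seed = config$seed + 10L)
  epochs <- if (recipe == "simulated") config$epochs_sim else config$epochs_exp
  train(init_model(spec), dataset,
        train_config(max_epochs = epochs, lr = config$lr,
                     seed = config$seed + 20L),
        verbose = verbose)
}

.study_baseline <- function(config, model, mode, dataset = NULL) {
  ref_basis <- synthesize_basis("maleic_acid",
                                maleic_acid_multiplets(config$fwhm_hz),
                                config$grid)
  sigma <- if (mode == "mean_noise") {
    stopifnot(!is.null(dataset))
    0.5 * 0.013 * dataset$ref_peak_height
  } else 0
  build_baseline(ref_basis, model, mode = mode, noise_sigma = sigma,
                 seed = config$seed + 30L)
}

#' Attribution completeness study
#'
#' Trains a model on the noiseless simulated recipe (or reuses a supplied
#' one), attributes the three equimolar fixtures (25, 5 and 1 mM of every
#' analyte) against the noiseless reference-only baseline, and reports
#' per-fixture per-node attribution totals, predictions, completeness
#' gaps and the mean absolute percent difference between totals and
#' predictions.
#'
#' @param config An [experiment_config()].
#' @param model Optional pre-trained simulated-recipe model.
#' @param verbose Training verbosity.
#' @return List with the trained `model` and a named list of
#'   [attribution_report()]s (`equimolar_25`, `equimolar_5`,
#'   `equimolar_1`), plus `mapds`.
#' @export
run_completeness_study <- function(config, model = NULL, verbose = 0) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(model)) {
    ds <- .study_dataset(config, "simulated")
    model <- .study_model(config, ds, "simulated", verbose)
  }
  baseline <- .study_baseline(config, model, "noiseless")
  reports <- list()
  for (nm in c("equimolar_25", "equimolar_5", "equimolar_1")) {
    fx <- make_fixture(nm, config$grid, config$panel,
                       seed = config$seed + 40L, fwhm_hz = config$fwhm_hz)
    res <- attribute_all(model, fx$spectrum, baseline, config$ig)
    reports[[nm]] <- attribution_report(res, config$grid,
                                        node_names = names(config$panel))
  }
  list(model = model, reports = reports,
       mapds = vapply(reports, function(r) r$mapd, numeric(1)))
}

## ROIs of analyte b that do not intersect any ROI of analyte a
.nonoverlapping_rois <- function(analyte_rois, a, b) {
  Filter(function(rb) !any(vapply(analyte_rois[[a]], function(ra)
    rb$ppm_lo < ra$ppm_hi && ra$ppm_lo < rb$ppm_hi, logical(1))),
    analyte_rois[[b]])
}

#' Overlap-compensation study
#'
#' For the two overlapping analyte pairs of the default panel
#' (alanine/glutamine near 3.7 ppm and taurine/choline near 3.1 ppm),
#' sums each node's attribution over the partner analyte's
#' *non-overlapping* resonances, on the all-analytes equimolar 25 mM
#' fixture and on the six-analyte fixture with glutamine and taurine
#' removed. Overlap compensation shows up as a negative sum when the
#' partner is present, and vanishes when the partner is absent from the
#' input.
#'
#' @param config An [experiment_config()].
#' @param model Optional pre-trained simulated-recipe model.
#' @param verbose Training verbosity.
#' @return List with `compensation` (data frame: fixture, node, partner,
#'   sum in mM), the full cross-ROI matrices, and the model.
#' @export
run_overlap_study <- function(config, model = NULL, verbose = 0) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(model)) {
    ds <- .study_dataset(config, "simulated")
    model <- .study_model(config, ds, "simulated", verbose)
  }
  baseline <- .study_baseline(config, model, "noiseless")
  basis_set <- build_basis_set(config$grid, config$panel)
  ## the support threshold co-scales with the profile linewidth: at the
  ## widened scaled-down linewidths a 1% support would merge adjacent
  ## multiplets into one region and leave no non-overlapping partner ROI
  analyte_rois <- default_analyte_rois(basis_set,
                                       threshold = config$roi_threshold)
  pairs <- list(c("alanine", "glutamine"), c("glutamine", "alanine"),
                c("taurine", "choline"), c("choline", "taurine"))
  out <- list(cross_roi = list(), compensation = NULL, model = model)
  for (nm in c("equimolar_25", "six_analytes_25_noisy")) {
    fx <- make_fixture(nm, config$grid, config$panel,
                       seed = config$seed + 41L, fwhm_hz = config$fwhm_hz)
    res <- attribute_all(model, fx$spectrum, baseline, config$ig)
    out$cross_roi[[nm]] <- cross_roi_matrix(res, analyte_rois, config$grid)
    for (pr in pairs) {
      rois_b <- .nonoverlapping_rois(analyte_rois, pr[1], pr[2])
      s <- sum(vapply(rois_b, function(r)
        roi_sum(res[[match(pr[1], names(config$panel))]], r, config$grid),
        numeric(1)))
      out$compensation <- rbind(out$compensation,
        data.frame(fixture = nm, node = pr[1], partner = pr[2],
                   partner_present = fx$conc[pr[2]] > 0, sum = s))
    }
  }
  rownames(out$compensation) <- NULL
  out
}

#' Training-regime comparison study
#'
#' Trains one model on the noiseless simulated recipe and one on the
#' experimental-like recipe (or reuses supplied models), then evaluates
#' both on identical noisy fixtures containing two interfering singlets.
#' Each model keeps its matching baseline (noiseless reference-only for
#' the simulated-recipe model, mean-noise for the experimental-like one).
#' For every fixture seed the audit sums each node's attribution in a
#' window around each singlet. Verdicts follow the nearest-analyte node
#' (the node a clean-trained model misassigns the singlet to):
#' `misattribution` when that node receives more than
#' `misattribution_frac` of some singlet's concentration-equivalent
#' scale, `rejection` when its |sum| stays within `rejection_mM` for
#' every singlet. The full per-node audit is also returned.
#'
#' @param config An [experiment_config()].
#' @param model_sim,model_exp Optional pre-trained models.
#' @param fixture_seeds Seeds of the evaluated fixtures (default three).
#' @param misattribution_frac Misattribution threshold as a fraction of
#'   the singlet scale, default 0.2.
#' @param rejection_mM Rejection threshold in mM, default 1.
#' @param verbose Training verbosity.
#' @return List with `audits` (data frame per fixture seed, singlet,
#'   model: max-over-nodes |attribution sum|, the singlet scale, and the
#'   per-fixture verdicts), `verdicts` (aggregated across seeds), the
#'   models, and per-model predictions on each fixture.
#' @export
run_regime_comparison <- function(config, model_sim = NULL,
                                  model_exp = NULL,
                                  fixture_seeds = NULL,
                                  misattribution_frac = 0.2,
                                  rejection_mM = 1, verbose = 0) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(fixture_seeds)) fixture_seeds <- config$seed + 100L + 0:2
  ds_exp <- NULL
  if (is.null(model_sim)) {
    ds <- .study_dataset(config, "simulated")
    model_sim <- .study_model(config, ds, "simulated", verbose)
  }
  if (is.null(model_exp)) {
    ds_exp <- .study_dataset(config, "experimental_like")
    model_exp <- .study_model(config, ds_exp, "experimental_like", verbose)
  }
  aug <- augmentation_config(config$grid, fwhm_hz = config$fwhm_hz)
  base_sim <- .study_baseline(config, model_sim, "noiseless")
  ref_basis <- synthesize_basis("maleic_acid",
                                maleic_acid_multiplets(config$fwhm_hz),
                                config$grid)
  ref_peak <- 13.3 * max(ref_basis$unit_intensities)
  base_exp <- build_baseline(ref_basis, model_exp, mode = "mean_noise",
                             noise_sigma = 0.5 * 0.013 * ref_peak,
                             seed = config$seed + 30L)
  fwhm_ppm <- config$fwhm_hz / config$grid$freq_mhz
  res_tbl <- panel_resonances(config$panel)
  audits <- NULL
  preds <- list()
  for (fs in fixture_seeds) {
    fx <- make_fixture("plus_two_singlets_noisy", config$grid, config$panel,
                       aug = aug, seed = fs, fwhm_hz = config$fwhm_hz)
    nearest <- vapply(fx$records$ppm, function(p)
      res_tbl$analyte[which.min(abs(res_tbl$ppm - p))], character(1))
    for (mdl in c("sim", "exp")) {
      model <- if (mdl == "sim") model_sim else model_exp
      baseline <- if (mdl == "sim") base_sim else base_exp
      res <- attribute_all(model, fx$spectrum, baseline, config$ig)
      A <- vapply(res, function(r)
        singlet_audit(r, fx$records, config$grid,
                      fwhm_ppm = fwhm_ppm)$attr_sum,
        numeric(nrow(fx$records)))
      A <- matrix(A, nrow = nrow(fx$records))
      audits <- rbind(audits, data.frame(
        fixture_seed = fs, model = mdl,
        singlet = seq_len(nrow(fx$records)),
        ppm = fx$records$ppm, conc = fx$records$conc,
        nearest = nearest,
        nearest_sum = A[cbind(seq_along(nearest),
                              match(nearest, names(config$panel)))],
        max_abs_sum = apply(abs(A), 1, max),
        max_sum = apply(A, 1, max)))
      preds[[paste(mdl, fs, sep = "_")]] <-
        forward(model, fx$spectrum)
    }
  }
  per_seed <- do.call(rbind, lapply(fixture_seeds, function(fs) {
    a_sim <- audits[audits$fixture_seed == fs & audits$model == "sim", ]
    a_exp <- audits[audits$fixture_seed == fs & audits$model == "exp", ]
    data.frame(fixture_seed = fs,
               misattribution = any(a_sim$nearest_sum >
                                      misattribution_frac * a_sim$conc),
               rejection = all(abs(a_exp$nearest_sum) <= rejection_mM))
  }))
  list(audits = audits, per_seed = per_seed,
       verdicts = list(
         misattribution = sum(per_seed$misattribution) >=
           ceiling(length(fixture_seeds) * 2 / 3),
         rejection = sum(per_seed$rejection) >=
           ceiling(length(fixture_seeds) * 2 / 3)),
       predictions = preds,
       model_sim = model_sim, model_exp = model_exp)
}
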