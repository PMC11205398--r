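#' Reference-only baseline for integrated gradients
#'
#' Integrated gradients needs a neutral baseline input x' representing the
#' absence of analyte signal. Here the baseline is a spectrum containing
#' only the quantitative reference compound at its fixed concentration —
#' the natural "zero analyte" input for spectra that always carry the
#' reference. For models trained on noiseless data the baseline is
#' noiseless (`mode = "noiseless"`); for models trained with noise
#' augmentation, noise at the mean training magnitude is added
#' (`mode = "mean_noise"`).
#'
#' @param ref_basis `nmr_basis` of the reference compound.
#' @param model The `mlp_model` the baseline will be used with (provides
#'   the normalization constant).
#' @param ref_conc Reference concentration (mM), default 13.3.
#' @param mode `"noiseless"` or `"mean_noise"`.
#' @param noise_sigma Noise sd in raw intensity units for `mean_noise`
#'   (typically half the maximum training noise sd).
#' @param seed Seed for the noise realization (required for
#'   reproducibility of `mean_noise` baselines).
#' @return An object of class `ig_baseline`: the normalized baseline
#'   vector `x`, the grid, a description, and the seed.
#' @export
build_baseline <- function(ref_basis, model, ref_conc = 13.3,
                           mode = c("noiseless", "mean_noise"),
                           noise_sigma = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref_basis, "nmr_basis"), inherits(model, "mlp_model"))
  if (is.null(model$norm_constant) || model$norm_constant <= 0)
    stop("model carries no normalization constant")
  v <- ref_conc * ref_basis$unit_intensities
  if (mode == "mean_noise") {
    if (noise_sigma < 0) stop("`noise_sigma` must be non-negative")
    if (is.null(seed)) stop("`mean_noise` baseline requires a seed")
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sigma))
  }
  structure(list(x = v / model$norm_constant, grid = ref_basis$grid,
                 description = paste0("reference_only_", mode),
                 ref_conc = ref_conc, seed = seed),
            class = "ig_baseline")
}

#' Integration configuration for integrated gradients
#'
#' @param m_steps Number of Riemann steps, default 128.
#' @param quadrature `"left_riemann"` (gradients at k/m, k = 1..m) or
#'   `"midpoint"` (at (k - 1/2)/m).
#' @param completeness_tolerance Target bound (mM) on the completeness gap
#'   |sum of scores - (F(x) - F(x'))| when `adaptive` step doubling is on.
#' @param adaptive Double `m_steps` until every node's completeness gap is
#'   within tolerance (capped at `m_max`).
#' @param m_max Step-count cap for adaptive refinement, default 4096.
#' @return An object of class `ig_config`.
#' @export
ig_config <- function(m_steps = 128,
                      quadrature = c("left_riemann", "midpoint"),
                      completeness_tolerance = 0.01,
                      adaptive = TRUE, m_max = 4096) {
  quadrature <- match.arg(quadrature)
  if (m_steps < 1) stop("`m_steps` must be at least 1")
  structure(list(m_steps = as.integer(m_steps), quadrature = quadrature,
                 completeness_tolerance = completeness_tolerance,
                 adaptive = adaptive, m_max = as.integer(m_max)),
            class = "ig_config")
}

## gradients of every output node averaged along the straight path from
## baseline to input; returns the n_in x n_out matrix of path-mean
## gradients. Chunked over steps to bound memory.
.path_mean_gradients <- function(model, x, xp, m, quadrature,
                                 chunk = 1024L) {
  alphas <- if (quadrature == "midpoint") (seq_len(m) - 0.5) / m
            else seq_len(m) / m
  n_in <- model$spec$n_in
  n_out <- model$spec$n_out
  acc <- matrix(0, n_in, n_out)
  for (i0 in seq(1L, m, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, m)
    Xp <- outer(alphas[idx], x - xp) + matrix(xp, length(idx), n_in,
                                              byrow = TRUE)
    for (node in seq_len(n_out)) {
      G <- .input_grad_batch(model, Xp, node)
      acc[, node] <- acc[, node] + colSums(G)
    }
  }
  acc / m
}

.new_attribution <- function(model, x, baseline, node, scores, m) {
  pred <- forward(model, x, normalized = TRUE)
  bpred <- forward(model, baseline$x, normalized = TRUE)
  structure(list(node = node, scores = scores, baseline = baseline,
                 input = x, m_steps = m,
                 prediction = pred[node], baseline_prediction = bpred[node],
                 completeness_gap = abs(sum(scores) -
                                          (pred[node] - bpred[node]))),
            class = "ig_attribution")
}

#' Integrated gradients for one output node
#'
#' Computes per-datapoint attribution scores for output `node` by the
#' integrated-gradients formula
#' IG_i = (x_i - x'_i) * (1/m) * sum_k dF(x' + a_k (x - x')) / dx_i,
#' with a_k = k/m (left Riemann) or (k - 1/2)/m (midpoint), where x' is
#' the reference-only baseline. Because the model outputs mM, the scores
#' are in mM per datapoint and their total approximates
#' F(x) - F(x') (the completeness axiom); the residual is reported as the
#' completeness gap. With `config$adaptive`, m is doubled until the gap
#' falls within tolerance or `m_max` is reached.
#'
#' @param model A trained `mlp_model`.
#' @param x Input spectrum in normalized coordinates (numeric vector), or
#'   an [nmr_spectrum()] in raw units (normalized internally).
#' @param baseline An [build_baseline()] result on the same grid.
#' @param node Output node index.
#' @param config An [ig_config()].
#' @return An object of class `ig_attribution`: `scores` (mM per
#'   datapoint), `prediction`, `baseline_prediction`, `completeness_gap`
#'   (all mM), the step count `m_steps` actually used, the baseline and
#'   the input.
#' @export
integrated_gradients <- function(model, x, baseline, node,
                                 config = ig_config()) {
  res <- attribute_all(model, x, baseline, config, nodes = node)
  res[[1]]
}

#' Integrated gradients for every output node
#'
#' Identical to per-node [integrated_gradients()] calls, but the path
#' forward passes are shared across nodes.
#'
#' @inheritParams integrated_gradients
#' @param nodes Output nodes to attribute (default all).
#' @return List of `ig_attribution`, one per requested node.
#' @export
attribute_all <- function(model, x, baseline, config = ig_config(),
                          nodes = NULL) {
  stopifnot(inherits(model, "mlp_model"), inherits(baseline, "ig_baseline"),
            inherits(config, "ig_config"))
  if (inherits(x, "nmr_spectrum")) {
    if (!grids_equal(x$grid, baseline$grid))
      stop("input and baseline grids differ")
    x <- x$intensities / model$norm_constant
  }
  x <- as.numeric(x)
  if (length(x) != model$spec$n_in)
    stop("input length does not match the model input layer")
  if (length(x) != length(baseline$x))
    stop("input and baseline lengths differ")
  if (is.null(nodes)) nodes <- seq_len(model$spec$n_out)
  dx <- x - baseline$x
  pred <- forward(model, x, normalized = TRUE)
  bpred <- forward(model, baseline$x, normalized = TRUE)
  m <- config$m_steps
  repeat {
    mg <- .path_mean_gradients(model, x, baseline$x, m, config$quadrature)
    gaps <- vapply(nodes, function(nd)
      abs(sum(dx * mg[, nd]) - (pred[nd] - bpred[nd])), numeric(1))
    if (!config$adaptive || all(gaps <= config$completeness_tolerance) ||
        2 * m > config$m_max) break
    m <- 2L * m
  }
  lapply(nodes, function(nd)
    .new_attribution(model, x, baseline, nd, dx * mg[, nd], m))
}

#' Completeness gap of an attribution
#'
#' The absolute difference between the attribution total and
#' F(x) - F(x'), in mM. Exactly zero for linear models; shrinks with the
#' step count for ReLU networks.
#'
#' @param result An `ig_attribution`.
#' @return Gap in mM.
#' @export
completeness_gap <- function(result) {
  stopifnot(inherits(result, "ig_attribution"))
  result$completeness_gap
}

#' @export
print.ig_attribution <- function(x, ...) {
  cat(sprintf(
    "<ig_attribution> node %d: total %.4g mM, prediction %.4g mM (baseline %.4g), gap %.3g mM, m = %d\n",
    x$node, sum(x$scores), x$prediction, x$baseline_prediction,
    x$completeness_gap, x$m_steps))
  invisible(x)
}
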