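#' Total attribution of an output node
#'
#' The sum of all attribution scores; by the completeness axiom this
#' approximates F(x) - F(x'), i.e. the predicted concentration relative to
#' the analyte-free baseline.
#'
#' @param result An `ig_attribution`.
#' @return Total in mM.
#' @export
attribution_total <- function(result) {
  stopifnot(inherits(result, "ig_attribution"))
  sum(result$scores)
}

#' Percent difference between attribution total and prediction
#'
#' 100 * |total - predicted| / |predicted|. Undefined (NA, with a warning)
#' for a zero prediction.
#'
#' @param total Attribution total (mM).
#' @param predicted Predicted concentration (mM).
#' @return Percent difference.
#' @export
percent_diff <- function(total, predicted) {
  if (any(predicted == 0)) {
    warning("zero prediction: percent difference undefined, returning NA")
    out <- rep(NA_real_, length(total))
    ok <- predicted != 0
    out[ok] <- 100 * abs(total[ok] - predicted[ok]) / abs(predicted[ok])
    return(out)
  }
  100 * abs(total - predicted) / abs(predicted)
}

#' Mean absolute percent difference over output nodes
#'
#' Averages [percent_diff()] between each node's attribution total and its
#' predicted concentration — the headline diagnostic of how faithfully
#' attribution sums track predictions.
#'
#' @param results List of `ig_attribution` (one per node).
#' @param predictions Optional numeric vector of predictions; defaults to
#'   the predictions stored on the results.
#' @return MAPD in percent.
#' @export
mapd <- function(results, predictions = NULL) {
  if (length(results) < 1) stop("need at least one attribution result")
  totals <- vapply(results, attribution_total, numeric(1))
  if (is.null(predictions))
    predictions <- vapply(results, function(r) r$prediction, numeric(1))
  mean(percent_diff(totals, predictions))
}

#' Region of interest on the ppm axis
#'
#' @param name ROI label.
#' @param ppm_lo,ppm_hi Window bounds in ppm (`ppm_lo < ppm_hi`). The
#'   window is half-open, lower-inclusive: `[ppm_lo, ppm_hi)`.
#' @param analyte Optional analyte the ROI belongs to.
#' @return An object of class `nmr_roi`.
#' @export
roi <- function(name, ppm_lo, ppm_hi, analyte = NULL) {
  if (ppm_lo >= ppm_hi) stop("`ppm_lo` must be below `ppm_hi`")
  structure(list(name = name, ppm_lo = ppm_lo, ppm_hi = ppm_hi,
                 analyte = analyte),
            class = "nmr_roi")
}

#' Sum attribution scores over a region of interest
#'
#' Sums scores at grid points with ppm in `[ppm_lo, ppm_hi)`. ROIs that
#' partition the window therefore add up to the node total exactly.
#'
#' @param result An `ig_attribution`.
#' @param roi An [roi()].
#' @param grid The [nmr_grid()] the scores live on.
#' @return ROI sum in mM.
#' @export
roi_sum <- function(result, roi, grid) {
  stopifnot(inherits(result, "ig_attribution"), inherits(roi, "nmr_roi"))
  ax <- ppm_axis(grid)
  sum(result$scores[ax >= roi$ppm_lo & ax < roi$ppm_hi])
}

#' Derive per-analyte ROIs from basis spectra
#'
#' Finds, for each analyte, the contiguous ppm regions where its unit
#' basis spectrum exceeds `threshold` times its own maximum. This avoids
#' hand-tuned windows and adapts automatically to the panel's shift table
#' and linewidth.
#'
#' @param basis_set Named list of `nmr_basis`.
#' @param threshold Fraction of the per-analyte maximum, default 0.01.
#' @return Named list (per analyte) of [roi()] lists.
#' @export
default_analyte_rois <- function(basis_set, threshold = 0.01) {
  out <- lapply(names(basis_set), function(a) {
    b <- basis_set[[a]]
    ax <- ppm_axis(b$grid)
    h <- grid_spacing(b$grid)
    above <- b$unit_intensities > threshold * max(b$unit_intensities)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    lapply(seq_along(idx), function(k) {
      i0 <- starts[idx[k]]; i1 <- ends[idx[k]]
      roi(sprintf("%s_%d", a, k), ax[i0] - h / 2, ax[i1] + h / 2, analyte = a)
    })
  })
  stats::setNames(out, names(basis_set))
}

#' Cross-analyte ROI attribution matrix
#'
#' Entry (i, j) sums node i's attribution scores over every ROI of
#' analyte j. Diagonal entries capture each node's attribution at its own
#' resonances; negative off-diagonal entries at a partner's
#' non-overlapping resonances are the signature of overlap compensation.
#'
#' @param results List of `ig_attribution`, one per node, in panel order.
#' @param analyte_rois Named list of ROI lists (see
#'   [default_analyte_rois()]).
#' @param grid The [nmr_grid()] of the scores.
#' @param node_names Optional row names (defaults to analyte names when
#'   the counts agree).
#' @return Matrix (n_nodes x n_analytes) of mM sums.
#' @export
cross_roi_matrix <- function(results, analyte_rois, grid,
                             node_names = NULL) {
  if (any(vapply(analyte_rois, length, integer(1)) < 1))
    stop("every analyte needs at least one ROI")
  M <- vapply(analyte_rois, function(rois) {
    vapply(results, function(res)
      sum(vapply(rois, function(r) roi_sum(res, r, grid), numeric(1))),
      numeric(1))
  }, numeric(length(results)))
  M <- matrix(M, nrow = length(results),
              dimnames = list(
                if (!is.null(node_names)) node_names
                else if (length(results) == length(analyte_rois))
                  names(analyte_rois) else NULL,
                names(analyte_rois)))
  M
}

#' Audit attribution assigned to inserted singlets
#'
#' Sums a node's attribution scores in a window around each inserted
#' singlet. A model trained without interfering signals misattributes
#' singlets to nearby analytes (large sums); a model trained with random
#' singlets rejects them (sums near zero).
#'
#' @param result An `ig_attribution`.
#' @param singlet_records Data frame from [add_singlets()] /
#'   [make_fixture()] with a `ppm` column.
#' @param grid The [nmr_grid()] of the scores.
#' @param window_halfwidth Audit half-width in ppm; default 5 times the
#'   singlet linewidth `fwhm_ppm` if given, else 0.05 ppm.
#' @param fwhm_ppm Singlet linewidth (ppm) used for the default half-width.
#' @return Data frame with columns `ppm`, `conc` (if present in the
#'   records) and `attr_sum` (mM); zero rows when no singlets were
#'   inserted.
#' @export
singlet_audit <- function(result, singlet_records, grid,
                          window_halfwidth = NULL, fwhm_ppm = NULL) {
  stopifnot(inherits(result, "ig_attribution"))
  if (is.null(window_halfwidth))
    window_halfwidth <- if (!is.null(fwhm_ppm)) 5 * fwhm_ppm else 0.05
  if (nrow(singlet_records) == 0)
    return(data.frame(ppm = numeric(0), conc = numeric(0),
                      attr_sum = numeric(0)))
  sums <- vapply(singlet_records$ppm, function(p)
    roi_sum(result, roi("singlet", p - window_halfwidth,
                        p + window_halfwidth), grid),
    numeric(1))
  out <- singlet_records
  out$attr_sum <- sums
  out
}

#' Pairwise attribution similarity between output nodes
#'
#' Cosine similarity between the per-node score vectors. Node pairs whose
#' attributions are nearly identical (similarity at or above `threshold`)
#' are flagged: such pairs predict from the same evidence, the signature
#' of a training-panel bias (e.g. two output quantities represented by a
#' single compound in training).
#'
#' @param results List of `ig_attribution` (at least two).
#' @param threshold Flagging threshold, default 0.99.
#' @param node_names Optional names for rows/columns.
#' @return List with `similarity` (symmetric matrix) and `flags` (data
#'   frame of flagged pairs with their similarity).
#' @export
node_similarity <- function(results, threshold = 0.99, node_names = NULL) {
  if (length(results) < 2) stop("need at least two nodes")
  S <- vapply(results, function(r) r$scores,
              numeric(length(results[[1]]$scores)))
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  Sn <- sweep(S, 2, nrm, "/")
  sim <- crossprod(Sn)
  dimnames(sim) <- list(node_names, node_names)
  pairs <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  flags <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                      similarity = sim[pairs])
  if (!is.null(node_names)) {
    flags$node_a <- node_names[flags$node_a]
    flags$node_b <- node_names[flags$node_b]
  }
  list(similarity = sim, flags = flags)
}

#' Assemble a quantitative attribution report
#'
#' @param results List of `ig_attribution`, one per node.
#' @param grid The [nmr_grid()] of the scores.
#' @param analyte_rois Optional named ROI lists for the cross-analyte
#'   matrix.
#' @param singlet_records Optional singlet records for the audit.
#' @param node_names Node labels (defaults to analyte names if
#'   `analyte_rois` matches).
#' @param similarity_threshold Bias-flag threshold for
#'   [node_similarity()].
#' @param fwhm_ppm Singlet linewidth for the audit window.
#' @return An object of class `attribution_report` with per-node totals,
#'   predictions, percent differences, completeness gaps, MAPD, and (when
#'   inputs allow) the cross-analyte ROI matrix, singlet audit and node
#'   similarity.
#' @export
attribution_report <- function(results, grid, analyte_rois = NULL,
                               singlet_records = NULL, node_names = NULL,
                               similarity_threshold = 0.99,
                               fwhm_ppm = NULL) {
  totals <- vapply(results, attribution_total, numeric(1))
  preds <- vapply(results, function(r) r$prediction, numeric(1))
  gaps <- vapply(results, completeness_gap, numeric(1))
  if (is.null(node_names) && !is.null(analyte_rois) &&
      length(results) == length(analyte_rois))
    node_names <- names(analyte_rois)
  tab <- data.frame(node = node_names %||% seq_along(results),
                    attribution_total = totals, prediction = preds,
                    percent_diff = percent_diff(totals, preds),
                    completeness_gap = gaps,
                    m_steps = vapply(results, function(r) r$m_steps,
                                     numeric(1)))
  out <- list(per_node = tab, mapd = mean(tab$percent_diff),
              cross_roi = NULL, singlet_audit = NULL, similarity = NULL)
  if (!is.null(analyte_rois))
    out$cross_roi <- cross_roi_matrix(results, analyte_rois, grid,
                                      node_names)
  if (!is.null(singlet_records) && nrow(singlet_records) > 0)
    out$singlet_audit <- do.call(rbind, lapply(seq_along(results),
      function(i) {
        a <- singlet_audit(results[[i]], singlet_records, grid,
                           fwhm_ppm = fwhm_ppm)
        a$node <- tab$node[i]
        a
      }))
  if (length(results) >= 2)
    out$similarity <- node_similarity(results, similarity_threshold,
                                      node_names)
  structure(out, class = "attribution_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report>\n")
  print(x$per_node, row.names = FALSE)
  cat(sprintf("MAPD: %.4g %%\n", x$mapd))
  if (!is.null(x$similarity) && nrow(x$similarity$flags) > 0) {
    cat("flagged near-identical node pairs:\n")
    print(x$similarity$flags, row.names = FALSE)
  }
  invisible(x)
}

#' Export a report to CSV/JSON (and optionally a plot)
#'
#' Writes `per_node.csv`, `cross_roi.csv`, `singlet_audit.csv`,
#' `similarity.csv` (as available), a `summary.json`, and optionally a
#' stacked attribution plot.
#'
#' @param report An [attribution_report()].
#' @param dir Output directory (created if needed).
#' @param results Optional list of `ig_attribution` to plot.
#' @param grid Grid for the plot axis.
#' @param plot Write `attributions.pdf` when `TRUE`.
#' @param scale_max_1 Scale each node's scores to max 1.0 in the plot.
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir, results = NULL, grid = NULL,
                          plot = FALSE, scale_max_1 = FALSE) {
  stopifnot(inherits(report, "attribution_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_node, file.path(dir, "per_node.csv"),
                   row.names = FALSE)
  if (!is.null(report$cross_roi))
    utils::write.csv(as.data.frame(report$cross_roi),
                     file.path(dir, "cross_roi.csv"))
  if (!is.null(report$singlet_audit))
    utils::write.csv(report$singlet_audit,
                     file.path(dir, "singlet_audit.csv"), row.names = FALSE)
  if (!is.null(report$similarity))
    utils::write.csv(as.data.frame(report$similarity$similarity),
                     file.path(dir, "similarity.csv"))
  jsonlite::write_json(
    list(mapd = report$mapd,
         totals = report$per_node$attribution_total,
         predictions = report$per_node$prediction,
         completeness_gaps = report$per_node$completeness_gap,
         flagged_pairs = if (!is.null(report$similarity))
           report$similarity$flags else NULL),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (plot && !is.null(results) && !is.null(grid)) {
    grDevices::pdf(file.path(dir, "attributions.pdf"), width = 8,
                   height = 1.2 * length(results))
    on.exit(grDevices::dev.off())
    plot_attributions(results, grid, node_names = report$per_node$node,
                      scale_max_1 = scale_max_1)
  }
  invisible(dir)
}

#' Stacked per-node attribution plot
#'
#' Draws each node's attribution scores as a stacked trace over the
#' (conventionally reversed) ppm axis.
#'
#' @param results List of `ig_attribution`.
#' @param grid The [nmr_grid()] of the scores.
#' @param node_names Trace labels.
#' @param scale_max_1 Scale each trace to a maximum of 1.0 so small
#'   signals stay visible.
#' @export
plot_attributions <- function(results, grid, node_names = NULL,
                              scale_max_1 = FALSE) {
  ax <- ppm_axis(grid)
  n <- length(results)
  S <- lapply(results, function(r) r$scores)
  if (scale_max_1)
    S <- lapply(S, function(s) if (max(abs(s)) > 0) s / max(abs(s)) else s)
  amp <- max(vapply(S, function(s) max(abs(s)), numeric(1)))
  graphics::plot(NULL, xlim = c(grid$ppm_max, grid$ppm_min),
                 ylim = c(0, n + 1), yaxt = "n",
                 xlab = "chemical shift (ppm)", ylab = "")
  for (i in seq_len(n)) {
    graphics::lines(ax, i + 0.45 * S[[i]] / amp, lwd = 0.5)
    graphics::text(grid$ppm_max, i + 0.3,
                   labels = (node_names %||% seq_len(n))[i], adj = 0,
                   cex = 0.7)
  }
  invisible(NULL)
}
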