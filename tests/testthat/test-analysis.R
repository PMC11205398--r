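## hand-built attribution results on a small grid for the bookkeeping tests
fake_result <- function(scores, prediction = sum(scores), node = 1L,
                        baseline_prediction = 0) {
  structure(list(node = node, scores = scores, baseline = NULL,
                 input = NULL, m_steps = 1L, prediction = prediction,
                 baseline_prediction = baseline_prediction,
                 completeness_gap = abs(sum(scores) -
                                          (prediction - baseline_prediction))),
            class = "ig_attribution")
}

grid_an <- nmr_grid(0, 10, 101, 400)

test_that("totals, percent differences and MAPD follow their definitions", {
  r <- fake_result(rep(0, 101))
  expect_equal(attribution_total(r), 0)

  expect_equal(percent_diff(24.9, 25.0), 0.4)
  expect_equal(percent_diff(25, 25), 0)
  expect_warning(pd <- percent_diff(1, 0), "zero prediction")
  expect_true(is.na(pd))

  r1 <- fake_result(rep(0.1, 101), prediction = 10)   # total 10.1
  r2 <- fake_result(rep(0.2, 101), prediction = 20.1) # total 20.2
  expect_equal(mapd(list(r1, r2)),
               mean(c(100 * 0.1 / 10, 100 * abs(20.2 - 20.1) / 20.1)))
})

test_that("roi sums are half-open, lower-inclusive, and partition-additive", {
  set.seed(1)
  scores <- rnorm(101)
  r <- fake_result(scores)
  full <- roi("full", -0.05, 10.05)
  expect_equal(roi_sum(r, full, grid_an), attribution_total(r))

  ## half-open convention: a boundary exactly on a grid point goes left-in
  left <- roi("l", -0.05, 5)
  right <- roi("r", 5, 10.05)
  expect_equal(roi_sum(r, left, grid_an), sum(scores[1:50]))
  expect_equal(roi_sum(r, right, grid_an), sum(scores[51:101]))
  expect_equal(roi_sum(r, left, grid_an) + roi_sum(r, right, grid_an),
               attribution_total(r))

  ## any finer partition still adds to the total exactly
  cuts <- c(-0.05, sort(runif(7, 0, 10)), 10.05)
  parts <- vapply(seq_len(8), function(i)
    roi_sum(r, roi("p", cuts[i], cuts[i + 1]), grid_an), numeric(1))
  expect_equal(sum(parts), attribution_total(r))

  expect_error(roi("bad", 3, 2), "below")
})

test_that("derived analyte ROIs cover each basis above threshold", {
  g <- nmr_grid(0, 10, 4001, 400)
  bs <- build_basis_set(g, list(
    one = list(multiplet(2, "singlet", fwhm_hz = 40, n_protons = 1)),
    two = list(multiplet(4, "singlet", fwhm_hz = 40, n_protons = 1),
               multiplet(8, "singlet", fwhm_hz = 40, n_protons = 1))))
  rois <- default_analyte_rois(bs)
  expect_length(rois$one, 1)
  expect_length(rois$two, 2)
  ## each ROI brackets its line centre
  expect_true(rois$one[[1]]$ppm_lo < 2 && rois$one[[1]]$ppm_hi > 2)
  expect_true(rois$two[[2]]$ppm_lo < 8 && rois$two[[2]]$ppm_hi > 8)
  ## support above threshold is inside the ROIs
  ax <- ppm_axis(g)
  y <- bs$two$unit_intensities
  inside <- (ax >= rois$two[[1]]$ppm_lo & ax < rois$two[[1]]$ppm_hi) |
    (ax >= rois$two[[2]]$ppm_lo & ax < rois$two[[2]]$ppm_hi)
  expect_true(all(y[!inside] <= 0.011 * max(y)))
})

test_that("the cross-analyte matrix reduces to ROI sums and zeroes out", {
  g <- nmr_grid(0, 10, 1001, 400)
  rois <- list(a = list(roi("a", 1.5, 2.5, "a")),
               b = list(roi("b1", 3.5, 4.5, "b"), roi("b2", 7.5, 8.5, "b")))
  set.seed(2)
  res <- list(fake_result(rnorm(1001)), fake_result(rnorm(1001)))
  M <- cross_roi_matrix(res, rois, g)
  expect_equal(dim(M), c(2, 2))
  expect_equal(M[1, "b"],
               roi_sum(res[[1]], rois$b[[1]], g) +
                 roi_sum(res[[1]], rois$b[[2]], g))
  zero <- list(fake_result(rep(0, 1001)), fake_result(rep(0, 1001)))
  expect_true(all(cross_roi_matrix(zero, rois, g) == 0))
  expect_error(cross_roi_matrix(res, list(a = list()), g), "at least one")
})

test_that("singlet audits report one window sum per inserted singlet", {
  r <- fake_result(c(rep(0, 40), rep(1, 21), rep(0, 40)))
  empty <- singlet_audit(r, data.frame(ppm = numeric(0),
                                       conc = numeric(0)), grid_an)
  expect_equal(nrow(empty), 0)

  recs <- data.frame(ppm = 5, conc = 10)
  a <- singlet_audit(r, recs, grid_an, window_halfwidth = 1.05)
  expect_equal(a$attr_sum, 21)  # all the nonzero scores sit in the window
  a2 <- singlet_audit(r, recs, grid_an, fwhm_ppm = 0.21)
  expect_equal(a2$attr_sum, 21)
})

test_that("node similarity flags near-identical attribution vectors", {
  set.seed(3)
  v <- rnorm(101)
  w <- rnorm(101)
  w <- w - sum(w * v) / sum(v * v) * v  # orthogonalize
  same <- node_similarity(list(fake_result(v), fake_result(v * 2)))
  expect_equal(same$similarity[1, 2], 1.0)
  expect_equal(nrow(same$flags), 1)

  orth <- node_similarity(list(fake_result(v), fake_result(w)))
  expect_equal(orth$similarity[1, 2], 0, tolerance = 1e-12)
  expect_equal(nrow(orth$flags), 0)
})

test_that("duplicated training targets produce flagged attribution pairs", {
  ## two output nodes supervised with the same target learn the same
  ## function, the constructed bias the similarity flag is meant to catch
  g <- nmr_grid(0, 10, 120, 400)
  panel <- list(
    a = list(multiplet(2.5, "singlet", fwhm_hz = 100, n_protons = 2)),
    b = list(multiplet(7.5, "singlet", fwhm_hz = 100, n_protons = 2)))
  ds <- generate_dataset("simulated",
                         list(n_all = 150, n_dropout = 150,
                              n_validation = 10),
                         g, panel = panel, seed = 5, fwhm_hz = 100)
  ## third output duplicates analyte b's labels
  ds$concentrations <- cbind(ds$concentrations,
                             dup = ds$concentrations[, "b"])
  m <- train(init_model(model_spec(120, 16, 3, seed = 2)), ds,
             train_config(batch_size = 32, max_epochs = 600, lr = 5e-3,
                          seed = 3))
  rb <- synthesize_basis("ref", maleic_acid_multiplets(100), g)
  baseline <- build_baseline(rb, m, mode = "noiseless")
  fx <- mix(build_basis_set(g, panel), c(a = 20, b = 30), rb)
  res <- attribute_all(m, fx, baseline,
                       ig_config(m_steps = 256, adaptive = FALSE))
  ns <- node_similarity(res, threshold = 0.99,
                        node_names = c("a", "b", "dup"))
  expect_true(any(ns$flags$node_a == "b" & ns$flags$node_b == "dup"))
  expect_false(any(ns$flags$node_a == "a"))
})

test_that("reports assemble and export to csv/json round-trippably", {
  set.seed(4)
  res <- list(fake_result(rnorm(101), node = 1L),
              fake_result(rnorm(101), node = 2L))
  rois <- list(n1 = list(roi("n1", 1, 3, "n1")),
               n2 = list(roi("n2", 6, 9, "n2")))
  rep_ <- attribution_report(res, grid_an, analyte_rois = rois,
                             singlet_records = data.frame(ppm = 5,
                                                          conc = 10))
  expect_equal(nrow(rep_$per_node), 2)
  expect_equal(rep_$per_node$node, c("n1", "n2"))
  expect_equal(rep_$mapd, mean(rep_$per_node$percent_diff))

  dir <- withr::local_tempdir()
  export_report(rep_, dir, results = res, grid = grid_an, plot = TRUE)
  expect_true(file.exists(file.path(dir, "per_node.csv")))
  expect_true(file.exists(file.path(dir, "attributions.pdf")))
  tab <- read.csv(file.path(dir, "per_node.csv"))
  expect_equal(nrow(tab), 2)
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$mapd, rep_$mapd, tolerance = 1e-12)
})
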