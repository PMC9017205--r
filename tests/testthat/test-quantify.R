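make_toy_cells <- function() {
  lab <- matrix(0L, 30, 30)
  lab[disk_mask(30, 5, c(10, 10))] <- 1L
  d2 <- disk_mask(30, 5, c(20, 21)); lab[d2 & lab == 0L] <- 2L
  label_map(lab, c("1" = "epithelial", "2" = "non_epithelial"))
}

toy_disk_area <- sum(disk_mask(30, 5, c(10, 10)))

test_that("per-cell measurement: constant channel, centroids, areas, conservation", {
  cells <- make_toy_cells()
  ch <- list(M = as_ci(matrix(57, 30, 30)))
  tab <- measure_cells(cells, ch)
  expect_equal(nrow(tab), 2L)                      # one row per label
  expect_setequal(tab$cell_id, c(1L, 2L))
  expect_equal(tab$mean_M, c(57, 57))
  expect_equal(tab$area_px, rep(toy_disk_area, 2))
  # 0-based x/y: x = col - 1, y = row - 1
  expect_equal(tab$x[tab$cell_id == 1], 9, tolerance = 1e-9)
  expect_equal(tab$y[tab$cell_id == 1], 9, tolerance = 1e-9)
  expect_equal(tab$compartment, c("epithelial", "non_epithelial"))
  expect_true(all(tab$circularity > 0 & tab$circularity <= 1))

  expect_error(measure_cells(cells, list(M = as_ci(matrix(0, 5, 5)))),
               "shape")
})

test_that("SSC-deleted signals are zeroed and flagged in the table", {
  cells <- make_toy_cells()
  img <- matrix(0, 30, 30)
  img[cells$labels == 1L] <- 400
  img[6:9, 6:9] <- 3000  # concentrate cell 1's signal
  ssc <- list(M = apply_ssc(cells, as_ci(img), ssc_params(0.5, 100)))
  tab <- measure_cells(cells, list(M = as_ci(img)), ssc)
  stat <- ssc$M$table
  del <- stat$cell_id[stat$status == "deleted"]
  expect_true(1L %in% del)
  expect_equal(tab$mean_M[tab$cell_id == 1L], 0)
  expect_equal(tab$ssc_deleted_M[tab$cell_id == 1L], 1L)
  expect_equal(tab$ssc_deleted_M[tab$cell_id == 2L], 0L)
})

test_that("QC filter: marker-count and size exclusions on a hand-written table", {
  tab <- data.frame(
    cell_id = 1:5, compartment = "non_epithelial", x = 0, y = 0,
    area_px = c(100, 150, 2500, 120, 90), circularity = 0.9,
    mean_A = c(500, 500, 500, 50, 500),
    mean_B = c(500, 500, 500, 500, 40),
    mean_C = c(500, 30, 500, 500, 30))
  class(tab) <- c("cell_table", "data.frame")
  # hand evaluation: cell 2 has 2 markers > 100 (removed), cell 3 too large,
  # cells 4 and 5 have 2 and 1 markers (removed); cell 1 survives
  out <- qc_filter(tab, min_markers_expressed = 3, max_area_px = 2000,
                   expression_floor = 100)
  expect_equal(out$cell_id, 1L)
  rem <- attr(out, "removed")
  expect_setequal(rem$cell_id, 2:5)
  expect_equal(rem$reason[rem$cell_id == 3], "area above maximum")

  # a cell with 2 expressed markers under a minimum of 3 is removed
  expect_false(2L %in% qc_filter(tab, 3, Inf, 100)$cell_id)
  # neutral settings are the identity
  expect_equal(qc_filter(tab, 0, Inf, 100)$cell_id, tab$cell_id)
})

test_that("SNR follows the staining/background ratio definitions", {
  img <- as_ci(matrix(50, 20, 20))
  img$pixels[1:5, 1:5] <- 500
  sig <- list(matrix(FALSE, 20, 20)); sig[[1]][1:5, 1:5] <- TRUE
  bg <- list(matrix(FALSE, 20, 20)); bg[[1]][10:15, 10:15] <- TRUE
  expect_equal(snr(sig, bg, img), 10)
  expect_equal(snr(sig, sig, img), 1)

  # hand-drawn 2-background-ROI toy: crypt variant averages per-ROI means
  img2 <- as_ci(matrix(0, 10, 10))
  img2$pixels[1:2, 1:2] <- 600             # signal
  img2$pixels[5, 1:4] <- 20                # background ROI 1 (4 px of 20)
  img2$pixels[9, 1:2] <- 100               # background ROI 2 (2 px of 100)
  s <- list(matrix(FALSE, 10, 10)); s[[1]][1:2, 1:2] <- TRUE
  b1 <- matrix(FALSE, 10, 10); b1[5, 1:4] <- TRUE
  b2 <- matrix(FALSE, 10, 10); b2[9, 1:2] <- TRUE
  # pooled: (4*20 + 2*100)/6 = 46.67; crypt: mean(20, 100) = 60
  expect_equal(snr(s, list(b1, b2), img2, "cell"), 600 / (280 / 6))
  expect_equal(snr(s, list(b1, b2), img2, "crypt"), 10)

  expect_error(snr(s, list(matrix(FALSE, 10, 10) == TRUE & FALSE,
                           b1 & FALSE), img2), "no signal|undefined")
})

test_that("gating replot reproduces exactly the selected footprints", {
  cells <- make_toy_cells()
  tab <- measure_cells(cells, list(M = as_ci(matrix(1, 30, 30))))
  expect_true(all(replot_gate(tab, integer(0), cells) == 0L))
  all_ov <- replot_gate(tab, tab$cell_id, cells)
  expect_identical(all_ov, cells$labels)
  one <- replot_gate(tab, 2L, cells)
  expect_identical(one == 2L, cells$labels == 2L)
  expect_true(all(one[cells$labels == 1L] == 0L))
  expect_error(replot_gate(tab, 99L, cells), "99")
})

test_that("gated synthetic Treg-like cells replot onto their true positions", {
  fix <- default_fixture()
  sc <- fix$scene
  tab <- fix$res$table
  map <- fix$match$map
  gate <- 100
  gated <- tab$cell_id[tab$mean_CD45 > gate & tab$mean_CD3 > gate &
                       tab$mean_CD4 > gate & tab$mean_Foxp3 > gate]
  truth_treg <- which(sc$marker_truth[, "CD45"] & sc$marker_truth[, "CD3"] &
                      sc$marker_truth[, "CD4"] & sc$marker_truth[, "Foxp3"])
  expect_gt(length(truth_treg), 0)
  expect_gt(length(gated), 0)
  # no false positives: every gated cell is a true Treg-like cell
  expect_true(all(map[as.character(gated)] %in% truth_treg))
  # and most true ones are found
  expect_gte(length(gated) / length(truth_treg), 0.7)
  ov <- replot_gate(tab, gated, fix$res$rois)
  expect_setequal(unique(ov[ov > 0]), gated)
})
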