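test_that("scene generation is reproducible and respects its invariants", {
  a <- make_scene(shape = c(256L, 256L), density = 5, seed = 5L)
  b <- make_scene(shape = c(256L, 256L), density = 5, seed = 5L)
  expect_identical(a, b)
  c2 <- make_scene(shape = c(256L, 256L), density = 5, seed = 6L)
  expect_false(identical(a$cells, c2$cells))

  expect_true(all(a$cells$a > 0 & a$cells$b > 0))
  expect_false(anyDuplicated(a$cells$id) > 0)
  if (nrow(a$spillover_edges) > 0) {
    expect_true(all(a$spillover_edges$strength > 0 &
                    a$spillover_edges$strength < 1))
    # at most one spillover event per victim and marker
    expect_false(anyDuplicated(a$spillover_edges[, c("victim", "marker")]) > 0)
  }
})

test_that("density 0 gives an empty scene that still renders", {
  sc <- make_scene(shape = c(128L, 128L), density = 0, seed = 1L)
  expect_equal(nrow(sc$cells), 0L)
  ch <- render_scene(sc)
  expect_equal(length(ch), nrow(sc$panel$markers))
  expect_true(all(dim(ch$DNA$pixels) == c(128, 128)))
})

test_that("declared exclusive pairs are never co-assigned", {
  sc <- make_scene(shape = c(448L, 448L), density = 8, seed = 31L)
  expect_gt(nrow(sc$cells), 150)
  for (pr in sc$exclusive_pairs)
    expect_equal(sum(sc$marker_truth[, pr[1]] & sc$marker_truth[, pr[2]]), 0L)
})

test_that("rendered nuclei count matches connected components when cells cannot touch", {
  # deterministically pick the first seed giving a layout with no touching
  # pair, then count nuclei by connected components of the render
  found <- FALSE
  for (seed in 41:80) {
    sc <- make_scene(shape = c(320L, 320L), density = 0.7,
                     epithelial_fraction = 0, seed = seed)
    if (nrow(sc$cells) < 2) next
    # conservative separation: even the longest semi-axes cannot touch
    d <- as.matrix(dist(sc$cells[, c("row", "col")]))
    diag(d) <- Inf
    if (min(d - outer(sc$cells$a, sc$cells$a, "+")) > 3) {
      found <- TRUE; break
    }
  }
  expect_true(found)
  ch <- render_scene(sc, noise_sd = 0, background = 0)
  lab <- EBImage::bwlabel(ch$DNA$pixels > 100)
  expect_equal(max(lab), nrow(sc$cells))
})

test_that("single positive cell confines its marker to that cell's region", {
  sc <- make_scene(shape = c(128L, 128L), density = 0.6,
                   epithelial_fraction = 0, spillover_rate = 0,
                   speckle_rate = 0, seed = 51L)
  expect_gte(nrow(sc$cells), 1)
  m <- "Vimentin"  # positive on every non-epithelial cell
  ch <- render_scene(sc, noise_sd = 0, background = 0)
  img <- ch[[m]]$pixels
  inside <- matrix(FALSE, sc$shape[1], sc$shape[2])
  for (i in seq_len(nrow(sc$cells)))
    inside[hmtiquant:::ellipse_indices(sc$cells$row[i], sc$cells$col[i],
                                       sc$cells$a[i], sc$cells$b[i],
                                       sc$cells$theta[i], sc$shape)] <- TRUE
  expect_true(all(img[!inside] == 0))
  expect_gt(sum(img[inside]), 0)
})

test_that("spillover artefacts put signal on the victim boundary facing the source", {
  sc <- small_scene()
  ed <- sc$spillover_edges
  expect_gt(nrow(ed), 0)
  ch <- render_scene(sc, noise_sd = 0, background = 0)
  k <- which.max(ed$strength)
  v <- ed$victim[k]; s <- ed$source[k]; m <- ed$marker[k]
  expect_false(sc$marker_truth[v, m])
  # crescent region: victim boundary band on the half facing the source
  cells <- sc$cells
  band <- setdiff(
    hmtiquant:::ellipse_indices(cells$row[v], cells$col[v], cells$a[v] + 3,
                                cells$b[v] + 3, cells$theta[v], sc$shape),
    hmtiquant:::ellipse_indices(cells$row[v], cells$col[v],
                                pmax(cells$a[v] - 3, 0.5),
                                pmax(cells$b[v] - 3, 0.5),
                                cells$theta[v], sc$shape))
  rc <- hmtiquant:::idx_rc(band, sc$shape[1])
  u <- c(cells$row[s] - cells$row[v], cells$col[s] - cells$col[v])
  facing <- (rc[, "row"] - cells$row[v]) * u[1] +
            (rc[, "col"] - cells$col[v]) * u[2] > 0
  expect_gt(mean(ch[[m]]$pixels[band[facing]]), 0)
})

test_that("raising the spillover rate monotonically raises the artefact burden", {
  rates <- c(0.05, 0.15, 0.5)
  scenes <- lapply(rates, function(r)
    make_scene(shape = c(320L, 320L), density = 8, seed = 61L,
               spillover_rate = r))
  # same layout, coupled acceptance: lower-rate edges nest in higher-rate
  expect_identical(scenes[[1]]$cells, scenes[[3]]$cells)
  key <- function(sc) paste(sc$spillover_edges$victim,
                            sc$spillover_edges$marker)
  expect_true(all(key(scenes[[1]]) %in% key(scenes[[2]])))
  expect_true(all(key(scenes[[2]]) %in% key(scenes[[3]])))

  # measured exclusive-pair double positives WITHOUT correction rise with
  # the rate (means over true ROIs of the pre-processed channels)
  dp <- vapply(scenes, function(sc) {
    ch <- render_scene(sc)
    rois <- scene_roi_map(sc)
    pp <- lapply(ch[c("CD4", "CD8")], preprocess_channel, class = "surface")
    tm <- truth_mean_table(sc, pp, rois)
    mean(tm$mean_CD4 > 100 & tm$mean_CD8 > 100)
  }, numeric(1))
  expect_true(all(diff(dp) >= 0))
  expect_gt(dp[3], dp[1])
})

test_that("an unreachable density errors out and reports what was achieved", {
  expect_error(make_scene(shape = c(128L, 128L), density = 80, seed = 1L),
               "achieved density")
})

test_that("ground-truth per-cell means are recoverable from a noiseless render", {
  sc <- small_scene()
  clean <- render_scene(sc, noise_sd = 0, background = 0)
  rois <- scene_roi_map(sc)
  tm <- truth_mean_table(sc, clean["DNA"], rois)
  # non-epithelial nuclei at 1000 over the footprint fraction of the ROI
  non <- sc$cells$compartment[tm$cell_id] == "non_epithelial"
  expect_true(all(tm$mean_DNA[non] > 300))
  expect_true(all(tm$mean_DNA[non] < 1000))
  epi <- !non
  # epithelial nuclei are dimmer by the configured factor
  expect_true(mean(tm$mean_DNA[epi]) < 0.5 * mean(tm$mean_DNA[non]))
})
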