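test_that("nuclei smoothing: identity at sigma 0, constant invariance, kernel response", {
  img <- as_ci(matrix(runif(400, 0, 100), 20, 20))
  expect_identical(preprocess_nuclei(img, 0)$pixels, img$pixels)
  expect_error(preprocess_nuclei(img, -1), "sigma")

  const <- as_ci(matrix(55, 33, 33))
  expect_equal(preprocess_nuclei(const, 1)$pixels, const$pixels,
               tolerance = 1e-6)

  # unit impulse: response equals the normalised discrete Gaussian kernel
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  got <- preprocess_nuclei(as_ci(imp), 1)$pixels
  want <- oracle_gaussian_center_response(1)
  half <- (nrow(want) - 1) / 2
  expect_equal(got[17 + (-half:half), 17 + (-half:half)], want,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("binarize: fixed threshold, Yen oracle equivalence, degenerate input", {
  x <- matrix(10, 10, 10); x[, 6:10] <- 200
  m <- binarize(as_ci(x), "fixed", fixed_threshold = 100)
  expect_identical(unclass(m)[, ], x > 100)
  expect_equal(attr(m, "threshold"), 100)

  # two-level image: Yen cut lies between the levels
  got <- binarize(as_ci(x), "yen")
  expect_identical(unclass(got)[, ], x > 100)
  o <- oracle_yen_mask(x)
  expect_identical(unclass(got)[, ], o$mask)

  # random 8-bit images against exhaustive criterion maximisation
  set.seed(303)
  for (rep in 1:6) {
    x <- rand_img(32, 32)
    got <- binarize(as_ci(x), "yen")
    expect_identical(unclass(got)[, ], oracle_yen_mask(x)$mask)
  }

  expect_true(!any(binarize(as_ci(matrix(0, 8, 8)), "fixed", 0)))
  expect_error(binarize(as_ci(matrix(3, 8, 8)), "otsu"), "degenerate")
  expect_error(binarize(as_ci(matrix(3, 8, 8)), "yen"), "degenerate")
  expect_error(binarize(as_ci(matrix(1:4, 2, 2)), "fixed"), "fixed_threshold")
})

test_that("watershed split: isolated disk stays whole, touching disks split", {
  m <- disk_mask(41, 10)
  lm <- split_touching(m)
  expect_equal(n_cells(lm), 1L)
  expect_identical(lm$labels > 0, m)

  # two overlapping disks of radius 10, centres 16 px apart
  m2 <- disk_mask(51, 10, c(26, 18)) | disk_mask(51, 10, c(26, 34))
  expect_equal(n_cells(split_touching(m2)), 2L)

  empty <- split_touching(matrix(FALSE, 10, 10))
  expect_equal(n_cells(empty), 0L)
})

test_that("particle filter applies the compartment gates and reports reasons", {
  # 50-px blob: below the epithelial 75-px minimum
  lab <- matrix(0L, 20, 20); lab[disk_mask(20, 3.9)] <- 1L
  expect_lt(sum(lab), 75)
  out <- filter_particles(label_map(lab), epithelial_particle_params())
  expect_equal(n_cells(out), 0L)
  expect_match(attr(out, "removed")$reason, "area below minimum")

  # elongated ~100-px blob passes circ 0.2 but fails circ 0.55
  lab2 <- matrix(0L, 40, 40); lab2[19:21, 4:37] <- 1L
  lm2 <- label_map(lab2)
  st <- filter_particles(lm2, particle_params(1, 4000, 0))
  expect_equal(n_cells(st), 1L)
  kept_epi <- filter_particles(lm2, epithelial_particle_params())
  kept_non <- filter_particles(lm2, non_epithelial_particle_params())
  expect_equal(n_cells(kept_epi), 1L)
  expect_equal(n_cells(kept_non), 0L)
  expect_match(attr(kept_non, "removed")$reason, "circularity")

  # idempotence
  twice <- filter_particles(kept_epi, epithelial_particle_params())
  expect_identical(twice$labels, kept_epi$labels)
})

test_that("circularity of a digital disk is in [0.85, 1] and matches Crofton", {
  m <- disk_mask(51, 20)
  lab <- matrix(0L, 51, 51); lab[m] <- 1L
  st <- hmtiquant:::label_stats(lab)
  expect_gte(st$circularity, 0.85)
  expect_lte(st$circularity, 1)
  p_impl <- hmtiquant:::perimeter_contour(m)
  p_crofton <- oracle_crofton_perimeter(m)
  expect_lt(abs(p_impl - p_crofton) / p_crofton, 0.10)
})

test_that("epithelial mask keeps only crypt-scale Yen-positive regions", {
  x <- matrix(10, 120, 120)
  big <- disk_mask(120, 26, c(40, 40))    # ~2120 px
  small <- disk_mask(120, 12, c(90, 90))  # ~450 px
  x[big] <- 900; x[small] <- 900
  m <- epithelial_mask(as_ci(x), min_region_px = 1000)
  expect_true(all(m[big]))
  expect_false(any(m[small]))

  # sparse sub-crypt-scale specks above threshold: nothing reaches 1000 px
  speck <- matrix(10, 100, 100)
  speck[disk_mask(100, 6, c(20, 20))] <- 800
  speck[disk_mask(100, 5, c(70, 60))] <- 900
  expect_equal(sum(epithelial_mask(as_ci(speck), 1000)), 0L)

  # crypt recovery on the synthetic scene: >= 95% of true epithelial pixels
  sc <- small_scene()
  ch <- small_channels()
  em <- epithelial_mask(ch$panCK, 1000)
  truth_px <- matrix(FALSE, sc$shape[1], sc$shape[2])
  for (k in seq_len(nrow(sc$crypts))) {
    cr <- sc$crypts[k, ]
    ann <- setdiff(
      hmtiquant:::ellipse_indices(cr$row, cr$col, cr$a_out, cr$b_out,
                                  cr$theta, sc$shape),
      hmtiquant:::ellipse_indices(cr$row, cr$col, cr$a_out - cr$thickness,
                                  cr$b_out - cr$thickness, cr$theta, sc$shape))
    truth_px[ann] <- TRUE
  }
  expect_gte(sum(em & truth_px) / sum(truth_px), 0.95)
})

test_that("ROI enlargement follows the distance-transform footprint and stays disjoint", {
  lab <- matrix(0L, 41, 41); lab[disk_mask(41, 10)] <- 1L
  lm <- label_map(lab)
  expect_identical(enlarge_rois(lm, 0)$labels, lab)

  grown <- enlarge_rois(lm, 3)
  # distance-transform oracle: pixels within 3 px (Euclidean) of any ROI
  # pixel, by brute-force minimum distance
  roi_rc <- which(lab == 1L, arr.ind = TRUE)
  want <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    d2 <- min((roi_rc[, 1] - i)^2 + (roi_rc[, 2] - j)^2)
    want[i, j] <- d2 <= 9 + 1e-9
  }
  expect_identical(grown$labels > 0, want)

  # two adjacent labels: enlarged ROIs stay disjoint and cover the gap
  lab2 <- matrix(0L, 34, 34)
  lab2[disk_mask(34, 6, c(17, 10))] <- 1L
  l2 <- disk_mask(34, 6, c(17, 25)); lab2[l2 & lab2 == 0L] <- 2L
  g2 <- enlarge_rois(label_map(lab2), 3)
  expect_true(all(g2$labels[lab2 > 0] == lab2[lab2 > 0]))
  gap <- g2$labels[17, 17:18]
  expect_true(all(gap > 0))
  # nearest-seed rule: midway pixels split between the two labels
  expect_setequal(unique(as.vector(g2$labels[17, 11:24])), c(1L, 2L))
})

test_that("two-pass segmentation recovers both compartments with disjoint labels", {
  sc <- small_scene()
  ch <- small_channels()
  lm <- segment_cells_by_type(ch$DNA, ch$panCK)
  expect_s3_class(lm, "label_map")
  expect_true(all(c("epithelial", "non_epithelial") %in% lm$compartment_of))
  # label ids and compartment table agree
  expect_setequal(as.integer(names(lm$compartment_of)),
                  sort(unique(lm$labels[lm$labels > 0])))

  mt <- match_labels(lm, sc)
  expect_gte(mt$precision, 0.9)
  expect_gte(mt$recall, 0.9)

  single <- segment_cells_single(ch$DNA)
  mt_single <- match_labels(single, sc)
  expect_gte(mt$recall, mt_single$recall)
  expect_gt(n_cells(lm), n_cells(single))
})

test_that("without a pan-cytokeratin channel segmentation falls back to a single wide pass", {
  sc <- make_scene(shape = c(256L, 256L), density = 6,
                   epithelial_fraction = 0, seed = 21L)
  ch <- render_scene(sc)
  with_crypts_absent <- segment_cells_by_type(ch$DNA, NULL)
  single <- segment_cells_single(ch$DNA)
  expect_equal(n_cells(with_crypts_absent), n_cells(single))
  expect_equal(attr(with_crypts_absent, "thresholds")[["single"]],
               attr(single, "threshold"))
})
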