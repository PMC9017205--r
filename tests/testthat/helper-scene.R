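# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small scene for module-level tests (fast)
small_scene <- function() cached("small_scene", function() {
  make_scene(shape = c(320L, 320L), density = 8, seed = 11L)
})

small_channels <- function() cached("small_channels", function() {
  render_scene(small_scene())
})

# majority-pixel matching of predicted labels to ground-truth cells:
# each predicted label is assigned to the truth cell holding the plurality
# of its pixels (background counts); one-to-one, extra claims are spurious.
match_labels <- function(pred_lm, scene) {
  truth <- scene_label_map(scene)$labels
  pix <- split(which(pred_lm$labels > 0), pred_lm$labels[pred_lm$labels > 0])
  match_id <- vapply(pix, function(idx) {
    tt <- table(truth[idx])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  matched <- match_id[match_id > 0]
  tp <- length(unique(matched))
  list(map = match_id,                       # names: pred label, value: truth id
       n_pred = length(pix),
       precision = if (length(pix)) tp / length(pix) else NA_real_,
       recall = if (nrow(scene$cells)) tp / nrow(scene$cells) else NA_real_)
}

# full-scale default fixture for the acceptance checks: default scene,
# pipeline run with SSC at defaults and with SSC disabled (threshold 1.0)
default_fixture <- function() cached("default_fixture", function() {
  out <- file.path(tempdir(), "hmtiq_fixture")
  demo <- make_demo(seed = 1L, out_dir = out)
  res <- run_all(demo$config)
  cfg_off <- demo$config
  cfg_off$ssc$fraction_threshold <- 1.0
  cfg_off$output_dir <- file.path(out, "results_nossc")
  res_nossc <- run_all(cfg_off)
  mt <- match_labels(res$segmentation, demo$scene)
  list(demo = demo, scene = demo$scene, res = res, res_nossc = res_nossc,
       match = mt, out = out)
})

# exclusive-pair double-positive fraction of a measured cell table
dp_fraction <- function(table, gate = 100, pair = c("CD4", "CD8")) {
  a <- table[[paste0("mean_", pair[1])]]
  b <- table[[paste0("mean_", pair[2])]]
  mean(a > gate & b > gate)
}

# spillover-artifact removal F1 over the default fixture at one threshold:
# artifact = above-gate instance on a truth-negative cell, genuine =
# above-gate instance on a truth-positive cell
artifact_f1 <- function(fix, threshold) {
  sc <- fix$scene
  map <- fix$match$map
  TP <- 0; FP <- 0; FN <- 0
  for (m in surface_markers(sc$panel)) {
    sw <- ssc_threshold_sweep(fix$res$rois, fix$res$channels[[m]], threshold)
    proc <- sw$cell_id[sw$status != "skipped_low_intensity"]
    del <- sw$cell_id[sw$status == "deleted"]
    tid <- map[as.character(proc)]
    ok <- !is.na(tid) & tid > 0
    neg <- proc[ok][!sc$marker_truth[tid[ok], m]]
    pos <- proc[ok][sc$marker_truth[tid[ok], m]]
    TP <- TP + length(intersect(del, neg))
    FN <- FN + length(setdiff(neg, del))
    FP <- FP + length(intersect(del, pos))
  }
  2 * TP / (2 * TP + FP + FN)
}

# disk-shaped logical mask centred in an n x n matrix
disk_mask <- function(n, r, ctr = c((n + 1) / 2, (n + 1) / 2)) {
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[ (g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= r^2, ])] <- TRUE
  m
}
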