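# End-to-end orchestration: stitch -> segment -> enlarge -> pre-process ->
# SSC -> measure -> QC -> export, with a structured run log that captures
# every parameter so a run can be reproduced exactly.

#' Pipeline run configuration
#'
#' Bundles every knob of the pipeline. All defaults equal the workflow's
#' stated values: blur sigma 1; particle gates 75–2000 px / circularity 0.2
#' (epithelial) and 70–400 px / 0.55 (non-epithelial); 3-px ROI enlargement;
#' 1000-px crypt minimum; SSC threshold 0.60 with intensity gate 100; QC
#' minimum of 3 expressed markers.
#'
#' @param input_dir directory holding the per-marker tile TIFFs.
#' @param output_dir directory the pipeline writes to.
#' @param panel a [panel_config].
#' @param grid a [tile_grid].
#' @param segmentation a [seg_config].
#' @param preprocess a [preprocess_params].
#' @param ssc an [ssc_params].
#' @param qc list with `min_markers_expressed`, `max_area_px`,
#'   `expression_floor`.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed identifies the run's data generation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir, panel = demo_panel(),
                       grid = tile_grid(2, 2, 32),
                       segmentation = seg_config(),
                       preprocess = preprocess_params(),
                       ssc = ssc_params(),
                       qc = list(min_markers_expressed = 3,
                                 max_area_px = 2000,
                                 expression_floor = 100),
                       seed = 1L) {
  stopifnot(inherits(panel, "panel_config"), inherits(grid, "tile_grid"),
            inherits(segmentation, "seg_config"),
            inherits(preprocess, "preprocess_params"),
            inherits(ssc, "ssc_params"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 panel = panel, grid = grid, segmentation = segmentation,
                 preprocess = preprocess, ssc = ssc, qc = qc,
                 seed = as.integer(seed)),
            class = "run_config")
}

# flatten a config into plain lists for YAML / JSON serialisation
config_as_list <- function(config) {
  list(
    input_dir = config$input_dir, output_dir = config$output_dir,
    seed = config$seed,
    panel = list(markers = config$panel$markers,
                 nuclei_marker = config$panel$nuclei_marker,
                 epithelial_marker = config$panel$epithelial_marker,
                 file_pattern = config$panel$file_pattern),
    grid = unclass(config$grid),
    segmentation = list(
      sigma = config$segmentation$sigma,
      threshold_method = config$segmentation$threshold_method,
      fixed_threshold = config$segmentation$fixed_threshold,
      epithelial = unclass(config$segmentation$epithelial),
      non_epithelial = unclass(config$segmentation$non_epithelial),
      enlarge_px = config$segmentation$enlarge_px,
      crypt_min_px = config$segmentation$crypt_min_px,
      watershed_h = config$segmentation$watershed_h),
    preprocess = unclass(config$preprocess),
    ssc = unclass(config$ssc),
    qc = config$qc)
}

#' Save / load a run configuration as YAML
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @return `save_run_config`: `path` invisibly; `load_run_config`: a
#'   [run_config].
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    input_dir = y$input_dir, output_dir = y$output_dir,
    panel = panel_config(as.data.frame(y$panel$markers),
                         y$panel$nuclei_marker, y$panel$epithelial_marker,
                         y$panel$file_pattern),
    grid = tile_grid(y$grid$n_rows, y$grid$n_cols, y$grid$overlap_px,
                     y$grid$order),
    segmentation = seg_config(
      sigma = y$segmentation$sigma,
      threshold_method = y$segmentation$threshold_method,
      fixed_threshold = y$segmentation$fixed_threshold,
      epithelial = do.call(particle_params, y$segmentation$epithelial),
      non_epithelial = do.call(particle_params, y$segmentation$non_epithelial),
      enlarge_px = y$segmentation$enlarge_px,
      crypt_min_px = y$segmentation$crypt_min_px,
      watershed_h = y$segmentation$watershed_h),
    preprocess = do.call(preprocess_params, y$preprocess),
    ssc = do.call(ssc_params, y$ssc),
    qc = y$qc, seed = y$seed)
}

#' Run the full quantification pipeline
#'
#' Executes, in order: tile stitching per marker; cell-type-specific
#' segmentation on the nuclei (and pan-cytokeratin) channel; ROI
#' enlargement; surface-marker pre-processing; spatial spillover correction
#' per surface marker; per-cell measurement; QC filtering; export (FCS +
#' CSV + label TIFF + SSC tables + JSON run log). Deterministic: repeated
#' runs on the same inputs produce byte-identical tables.
#'
#' @param config a [run_config]; all tile files for every configured marker
#'   must exist before any computation starts.
#' @return Invisibly, a list with `table` (post-QC `cell_table`),
#'   `table_preqc`, `rois` (enlarged [label_map]), `segmentation`
#'   (nucleus-level [label_map]), `ssc` (per-marker `ssc_result`),
#'   `channels` (processed channels) and `paths` of all written files.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panel <- config$panel
  grid <- config$grid
  # configuration errors before any computation
  expected <- list()
  for (m in panel$markers$name) {
    files <- character(0)
    for (i in seq_len(grid$n_rows * grid$n_cols)) {
      rc <- grid_position(grid, i)
      files <- c(files, file.path(config$input_dir,
                                  tile_filename(panel, m, rc[1], rc[2])))
    }
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
      stop(sprintf("configuration error: missing tile(s) for marker '%s': %s",
                   m, paste(basename(missing), collapse = ", ")))
    expected[[m]] <- files
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = config_as_list(config), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  channels <- stage("stitch", {
    ch <- lapply(panel$markers$name, function(m) {
      tiles <- lapply(seq_along(expected[[m]]), function(i)
        read_channel(expected[[m]][i], m))
      stitch_grid(tiles, grid)
    })
    names(ch) <- panel$markers$name
    ch
  })
  log$stages$stitch <- list(n_tiles = grid$n_rows * grid$n_cols,
                            overlap_px = grid$overlap_px,
                            stitched_shape = dim(channels[[1]]$pixels))

  seg <- stage("segment", {
    panck <- if (!is.null(panel$epithelial_marker))
      channels[[panel$epithelial_marker]] else NULL
    segment_cells_by_type(channels[[panel$nuclei_marker]], panck,
                          config$segmentation)
  })
  log$stages$segment <- list(
    n_cells = n_cells(seg),
    n_epithelial = sum(seg$compartment_of == "epithelial"),
    n_non_epithelial = sum(seg$compartment_of == "non_epithelial"),
    thresholds = as.list(attr(seg, "thresholds")),
    sigma = config$segmentation$sigma,
    threshold_method = config$segmentation$threshold_method,
    watershed_h = config$segmentation$watershed_h,
    epithelial_filter = unclass(config$segmentation$epithelial),
    non_epithelial_filter = unclass(config$segmentation$non_epithelial),
    crypt_min_px = config$segmentation$crypt_min_px)

  rois <- stage("enlarge", enlarge_rois(seg, config$segmentation$enlarge_px))
  log$stages$enlarge <- list(enlarge_px = config$segmentation$enlarge_px)

  processed <- stage("preprocess", {
    ch <- channels
    for (m in surface_markers(panel))
      ch[[m]] <- preprocess_channel(ch[[m]], "surface", config$preprocess)
    ch
  })
  log$stages$preprocess <- c(unclass(config$preprocess),
                             list(markers = surface_markers(panel)))

  ssc_res <- stage("ssc", {
    res <- lapply(surface_markers(panel), function(m)
      apply_ssc(rois, processed[[m]], config$ssc))
    names(res) <- surface_markers(panel)
    res
  })
  log$stages$ssc <- c(unclass(config$ssc), list(
    deleted_per_marker = lapply(ssc_res, function(r)
      sum(r$table$status == "deleted"))))

  table_preqc <- stage("quantify", measure_cells(rois, processed, ssc_res))
  log$stages$quantify <- list(n_cells = nrow(table_preqc),
                              n_parameters = ncol(table_preqc))

  table <- stage("qc", do.call(qc_filter, c(list(table_preqc), config$qc)))
  removed <- attr(table, "removed")
  log$stages$qc <- c(config$qc, list(
    n_removed = nrow(removed),
    removed_reasons = as.list(table(removed$reason))))

  paths <- stage("export", {
    p <- list(
      labels = file.path(out_dir, "cell_labels.tif"),
      rois = file.path(out_dir, "cell_rois.tif"),
      cells_csv = file.path(out_dir, "cells.csv"),
      cells_preqc_csv = file.path(out_dir, "cells_preqc.csv"),
      fcs = file.path(out_dir, "cells.fcs"),
      run_log = file.path(out_dir, "run_log.json"))
    write_label_map(seg, p$labels)
    write_label_map(rois, p$rois)
    write_cell_table(table, p$cells_csv)
    write_cell_table(table_preqc, p$cells_preqc_csv)
    export_fcs(table, p$fcs)
    for (m in names(ssc_res)) {
      f <- file.path(out_dir, sprintf("ssc_%s.csv", m))
      write_ssc_result(ssc_res[[m]], f)
      p[[paste0("ssc_", m)]] <- f
      dm <- ssc_res[[m]]$deleted_map
      if (any(dm > 0L)) {
        df <- file.path(out_dir, sprintf("ssc_deleted_%s.tif", m))
        tiff::writeTIFF(dm / 65535, df, bits.per.sample = 16L)
        p[[paste0("ssc_deleted_", m)]] <- df
      }
    }
    p
  })
  log$version <- as.character(utils::packageVersion("hmtiquant"))
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")

  invisible(list(table = table, table_preqc = table_preqc, rois = rois,
                 segmentation = seg, ssc = ssc_res, channels = processed,
                 raw_channels = channels, paths = paths, log = log))
}

#' Generate the demonstration dataset
#'
#' Builds the default synthetic scene, renders all channels, slices them
#' into the tile grid, and writes tiles, ground-truth tables and a ready
#' run configuration — the fixture the test suite and the worked examples
#' run on.
#'
#' @param seed scene seed.
#' @param out_dir directory to create the dataset in.
#' @param shape,density,... forwarded to [make_scene].
#' @param grid a [tile_grid] compatible with `shape`.
#' @return List with `scene`, `config` (a [run_config] whose `input_dir`
#'   points at the written tiles) and `paths`.
#' @export
make_demo <- function(seed = 1L, out_dir, shape = c(896L, 896L),
                      density = 8, grid = tile_grid(2, 2, 32), ...) {
  scene <- make_scene(shape = shape, density = density, seed = seed, ...)
  channels <- render_scene(scene)
  tile_dir <- file.path(out_dir, "tiles")
  dir.create(tile_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- scene$panel
  for (m in names(channels)) {
    tiles <- slice_tiles(channels[[m]], grid)
    for (i in seq_along(tiles)) {
      rc <- grid_position(grid, i)
      write_channel(tiles[[i]],
                    file.path(tile_dir, tile_filename(panel, m, rc[1], rc[2])))
    }
  }
  write_scene_truth(scene, file.path(out_dir, "truth"))
  config <- run_config(input_dir = tile_dir,
                       output_dir = file.path(out_dir, "results"),
                       panel = panel, grid = grid, seed = seed)
  cfg_path <- file.path(out_dir, "config.yaml")
  save_run_config(config, cfg_path)
  manifest <- list(seed = seed, shape = shape, n_cells = nrow(scene$cells),
                   n_epithelial = sum(scene$cells$compartment == "epithelial"),
                   n_spillover_edges = nrow(scene$spillover_edges))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(scene = scene, config = config,
       paths = list(tiles = tile_dir, truth = file.path(out_dir, "truth"),
                    config = cfg_path))
}
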