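# Per-cell feature measurement, QC exclusions, SNR evaluation and gating
# replot. The cells x parameters table is the hand-off point to
# flow-cytometry-style analysis.

#' Measure per-cell features across all markers
#'
#' For every cell (label) of the enlarged ROI map: mean intensity per marker
#' over the ROI (0 where the signal was SSC-deleted, with the paired
#' `ssc_deleted_<marker>` flag set), centroid (0-based x/y in stitched pixel
#' coordinates, x = column, y = row), pixel area and circularity.
#'
#' @param cells [label_map] of enlarged cell ROIs.
#' @param channels named list of [channel_image] — the pre-processed channel
#'   for surface markers, the raw channel otherwise; all must share the
#'   label map's shape.
#' @param ssc optional named list (marker -> `ssc_result`) from
#'   [apply_ssc].
#' @return A `cell_table`: data.frame with one row per cell and columns
#'   cell_id, compartment, x, y, area_px, circularity, `mean_<marker>`...,
#'   `ssc_deleted_<marker>`... (the latter only for markers with an SSC
#'   result).
#' @export
measure_cells <- function(cells, channels, ssc = NULL) {
  stopifnot(inherits(cells, "label_map"))
  for (m in names(channels))
    if (!all(dim(channels[[m]]$pixels) == dim(cells$labels)))
      stop(sprintf("channel '%s' shape differs from the label map", m))
  st <- label_stats(cells$labels)
  comp <- unname(cells$compartment_of[as.character(st$label)])
  tab <- data.frame(cell_id = st$label, compartment = comp,
                    x = st$col - 1, y = st$row - 1, area_px = st$area,
                    circularity = st$circularity)
  pix <- label_index(cells$labels)
  for (m in names(channels)) {
    px <- channels[[m]]$pixels
    mean_m <- vapply(pix, function(idx) mean(px[idx]), numeric(1))
    deleted <- rep(FALSE, nrow(tab))
    if (!is.null(ssc) && m %in% names(ssc)) {
      sc <- ssc[[m]]$table
      deleted <- tab$cell_id %in% sc$cell_id[sc$status == "deleted"]
      mean_m[deleted] <- 0
      tab[[paste0("ssc_deleted_", m)]] <- as.integer(deleted)
    }
    tab[[paste0("mean_", m)]] <- unname(mean_m)
  }
  # stable column order: features, then means, then flags
  mcols <- grep("^mean_", names(tab), value = TRUE)
  fcols <- grep("^ssc_deleted_", names(tab), value = TRUE)
  tab <- tab[, c("cell_id", "compartment", "x", "y", "area_px",
                 "circularity", mcols, fcols)]
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Quality-control filter on the cell table
#'
#' Removes cells expressing fewer than `min_markers_expressed` markers
#' (mean intensity above `expression_floor`, counted over all measured
#' markers) and unusually large cells (`area_px > max_area_px`). Defaults:
#' at least 3 markers; maximal area equal to the epithelial particle-filter
#' maximum (2000 px); expression floor equal to the SSC intensity gate.
#'
#' @param table a `cell_table` from [measure_cells].
#' @param min_markers_expressed minimal number of expressed markers.
#' @param max_area_px maximal cell area in pixels (`Inf` to disable).
#' @param expression_floor intensity above which a marker counts as
#'   expressed.
#' @return Filtered `cell_table` with attribute `removed` (cell_id,
#'   reason).
#' @export
qc_filter <- function(table, min_markers_expressed = 3, max_area_px = 2000,
                      expression_floor = 100) {
  stopifnot(min_markers_expressed >= 0, max_area_px >= 0,
            expression_floor >= 0)
  mcols <- grep("^mean_", names(table), value = TRUE)
  n_expr <- rowSums(as.matrix(table[, mcols, drop = FALSE]) > expression_floor)
  reason <- rep(NA_character_, nrow(table))
  reason[n_expr < min_markers_expressed] <- "fewer markers expressed than minimum"
  reason[table$area_px > max_area_px] <- "area above maximum"
  out <- table[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  attr(out, "removed") <- data.frame(cell_id = table$cell_id[!is.na(reason)],
                                     reason = reason[!is.na(reason)])
  out
}

#' Signal-to-noise ratio of signal ROIs against background ROIs
#'
#' Per signal ROI, the ratio of its mean intensity to the background level:
#' with `mode = "cell"` the background level is the mean over all pooled
#' background pixels; with `mode = "crypt"` it is the mean of the per-ROI
#' background means (the convention used for crypt-scale regions).
#'
#' @param signal_rois list of logical masks.
#' @param background_rois list of logical masks; total signal must be > 0.
#' @param img a [channel_image].
#' @param mode `"cell"` or `"crypt"`.
#' @return Numeric vector of per-signal-ROI SNR values.
#' @export
snr <- function(signal_rois, background_rois, img, mode = c("cell", "crypt")) {
  mode <- match.arg(mode)
  stopifnot(length(signal_rois) > 0, length(background_rois) > 0)
  bg_means <- vapply(background_rois, function(mk) mean(img$pixels[mk]),
                     numeric(1))
  bg_pool <- unlist(lapply(background_rois, function(mk) img$pixels[mk]))
  if (length(bg_pool) == 0 || sum(bg_pool) <= 0)
    stop("undefined SNR: background ROIs carry no signal")
  denom <- if (mode == "crypt") mean(bg_means) else mean(bg_pool)
  vapply(signal_rois, function(mk) mean(img$pixels[mk]) / denom, numeric(1))
}

#' Replot a gated cell population onto tissue coordinates
#'
#' Returns a label overlay containing exactly the footprints of the
#' selected cells, for rendering on any channel — the reconciliation of
#' gated populations with their original position in the tissue.
#'
#' @param table a `cell_table` (defines the known cell ids).
#' @param selected_ids cell ids to replot; must be a subset of the table.
#' @param cells the [label_map] the table was measured on.
#' @return Integer label matrix: 0 outside, original label on selected
#'   footprints.
#' @export
replot_gate <- function(table, selected_ids, cells) {
  selected_ids <- as.integer(selected_ids)
  unknown <- setdiff(selected_ids, table$cell_id)
  if (length(unknown) > 0)
    stop(sprintf("unknown cell id(s): %s",
                 paste(unknown, collapse = ", ")))
  overlay <- cells$labels
  overlay[!overlay %in% selected_ids] <- 0L
  overlay
}

#' Write a cell table as CSV
#'
#' Deterministic, lossless plain-text mirror of the FCS export.
#'
#' @param table a `cell_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
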