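# Spatial spillover correction (SSC): per cell and marker, signal
# concentrated in one quadrant of the ROI is deleted as neighbour-spillover
# or aggregate artefact.

#' SSC parameters
#'
#' Defaults are the workflow values: signals are deleted when one quadrant
#' holds more than 60% of the cell's total signal, and only cells with mean
#' intensity greater than 100 are corrected at all. The comparison is strict
#' (`>`), so `fraction_threshold = 1` disables deletion cleanly.
#' `fraction_threshold` must exceed 0.25: below that every uniformly stained
#' cell would be deleted.
#'
#' @param fraction_threshold maximal tolerated quadrant signal fraction, in
#'   `(0.25, 1]`.
#' @param min_mean_intensity intensity gate below which a cell is skipped.
#' @param fraction_mode `"sum"` (quadrant signal / total signal, default) or
#'   `"mean"` (quadrant mean / sum of quadrant means). For equal-area
#'   quadrants the two coincide; `sum` stays well-behaved for irregular
#'   ROIs.
#' @return An object of class `ssc_params`.
#' @export
ssc_params <- function(fraction_threshold = 0.60, min_mean_intensity = 100,
                       fraction_mode = c("sum", "mean")) {
  if (fraction_threshold <= 0.25 || fraction_threshold > 1)
    stop("fraction_threshold must be in (0.25, 1]")
  if (min_mean_intensity < 0) stop("min_mean_intensity must be >= 0")
  structure(list(fraction_threshold = fraction_threshold,
                 min_mean_intensity = min_mean_intensity,
                 fraction_mode = match.arg(fraction_mode)),
            class = "ssc_params")
}

#' Quadrant decomposition of a cell ROI
#'
#' Splits an ROI into four disjoint pixel sets at its centroid. Pixel
#' centres are compared to the centroid coordinates: pixels with
#' `row < centroid_row` go top, `col < centroid_col` go left — a
#' deterministic assignment whose union is the ROI.
#'
#' @param roi logical matrix (cell footprint), non-empty.
#' @param centroid `(row, col)`; default the ROI pixel-centre average.
#' @return Integer matrix of the ROI shape: 0 outside, quadrant 1 (top-left),
#'   2 (top-right), 3 (bottom-left), 4 (bottom-right) inside.
#' @export
quadrants_of <- function(roi, centroid = NULL) {
  stopifnot(is.matrix(roi))
  idx <- which(roi)
  if (length(idx) == 0L) stop("roi must be non-empty")
  rc <- idx_rc(idx, nrow(roi))
  if (is.null(centroid)) centroid <- c(mean(rc[, "row"]), mean(rc[, "col"]))
  q <- 1L + (rc[, "col"] >= centroid[2]) + 2L * (rc[, "row"] >= centroid[1])
  out <- matrix(0L, nrow(roi), ncol(roi))
  out[idx] <- q
  out
}

#' Quadrant signal fractions of one cell
#'
#' For each quadrant, the fraction of the cell's total signal it holds
#' (`fraction_mode = "sum"`), or the normalized quadrant means
#' (`fraction_mode = "mean"`). Fractions sum to 1. A cell with zero total
#' signal gets the uninformative `(0.25, 0.25, 0.25, 0.25)` with attribute
#' `flagged = TRUE` rather than a division error.
#'
#' @param img a [channel_image].
#' @param roi logical matrix, the cell footprint.
#' @param centroid `(row, col)` splitting point; default ROI centroid.
#' @param fraction_mode see [ssc_params].
#' @return Numeric vector of 4 fractions (q1..q4).
#' @export
spillover_fraction <- function(img, roi, centroid = NULL,
                               fraction_mode = "sum") {
  q <- quadrants_of(roi, centroid)
  idx <- which(roi)
  vals <- img$pixels[idx]
  qi <- q[idx]
  sums <- vapply(1:4, function(k) sum(vals[qi == k]), numeric(1))
  if (fraction_mode == "mean") {
    cnt <- tabulate(qi, 4L)
    sums <- ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
  }
  tot <- sum(sums)
  if (tot <= 0) {
    f <- rep(0.25, 4)
    attr(f, "flagged") <- TRUE
  } else {
    f <- sums / tot
    attr(f, "flagged") <- FALSE
  }
  names(f) <- paste0("q", 1:4)
  f
}

# Per-cell SSC profile: mean intensity and quadrant fractions, computed once
# so that several thresholds can be applied cheaply.
ssc_profile <- function(cells, channel, fraction_mode = "sum") {
  stopifnot(inherits(cells, "label_map"), inherits(channel, "channel_image"))
  if (!all(dim(cells$labels) == dim(channel$pixels)))
    stop("label map and channel shapes differ")
  pix <- label_index(cells$labels)
  ids <- as.integer(names(pix))
  n <- nrow(cells$labels)
  out <- data.frame(cell_id = ids, mean_intensity = NA_real_,
                    f1 = NA_real_, f2 = NA_real_, f3 = NA_real_,
                    f4 = NA_real_, flagged = FALSE)
  px <- channel$pixels
  for (i in seq_along(ids)) {
    idx <- pix[[i]]
    vals <- px[idx]
    out$mean_intensity[i] <- mean(vals)
    rc <- idx_rc(idx, n)
    ctr <- c(mean(rc[, "row"]), mean(rc[, "col"]))
    qi <- 1L + (rc[, "col"] >= ctr[2]) + 2L * (rc[, "row"] >= ctr[1])
    sums <- vapply(1:4, function(k) sum(vals[qi == k]), numeric(1))
    if (fraction_mode == "mean") {
      cnt <- tabulate(qi, 4L)
      sums <- ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
    }
    tot <- sum(sums)
    if (tot <= 0) {
      out[i, c("f1", "f2", "f3", "f4")] <- 0.25
      out$flagged[i] <- TRUE
    } else {
      out[i, c("f1", "f2", "f3", "f4")] <- sums / tot
    }
  }
  out
}

# Apply gate + threshold to a profile.
ssc_classify <- function(profile, params) {
  fmax <- pmax(profile$f1, profile$f2, profile$f3, profile$f4)
  status <- rep("retained", nrow(profile))
  status[fmax > params$fraction_threshold] <- "deleted"
  status[profile$mean_intensity <= params$min_mean_intensity] <-
    "skipped_low_intensity"
  status
}

#' Apply spatial spillover correction to one channel
#'
#' For each cell of the label map: cells at or below the intensity gate are
#' skipped; otherwise, if the largest quadrant signal fraction strictly
#' exceeds the threshold, the cell's signal on this marker is deleted
#' (downstream intensity set to 0) and the ROI archived for inspection;
#' otherwise it is retained.
#'
#' @param cells [label_map] of (enlarged) cell ROIs.
#' @param channel the [channel_image] the correction sees — for surface
#'   markers the pre-processed channel.
#' @param params an [ssc_params].
#' @return An object of class `ssc_result`: list with `table` (cell_id,
#'   mean_intensity, f1..f4, max_fraction, status), `deleted_map` (label
#'   matrix holding only the deleted ROIs, replottable onto the image),
#'   `marker`, and `params`.
#' @export
apply_ssc <- function(cells, channel, params = ssc_params()) {
  stopifnot(inherits(params, "ssc_params"))
  prof <- ssc_profile(cells, channel, params$fraction_mode)
  status <- ssc_classify(prof, params)
  prof$max_fraction <- pmax(prof$f1, prof$f2, prof$f3, prof$f4)
  prof$status <- status
  deleted <- prof$cell_id[status == "deleted"]
  dm <- cells$labels
  dm[!dm %in% deleted] <- 0L
  structure(list(table = prof, deleted_map = dm, marker = channel$marker,
                 params = params), class = "ssc_result")
}

#' @export
print.ssc_result <- function(x, ...) {
  cat(sprintf("<ssc_result> %s: %d retained, %d deleted, %d skipped (gate %g, threshold %g)\n",
              x$marker, sum(x$table$status == "retained"),
              sum(x$table$status == "deleted"),
              sum(x$table$status == "skipped_low_intensity"),
              x$params$min_mean_intensity, x$params$fraction_threshold))
  invisible(x)
}

#' Sweep the SSC fraction threshold
#'
#' Computes the per-cell quadrant profile once and classifies it under a
#' series of thresholds — the cheap way to study deletion behaviour as a
#' function of the threshold.
#'
#' @param cells [label_map] of cell ROIs.
#' @param channel the channel the correction sees.
#' @param thresholds numeric vector of fraction thresholds.
#' @param params base [ssc_params] (gate and fraction mode are taken from
#'   it).
#' @return data.frame with one row per (threshold, cell): threshold,
#'   cell_id, status.
#' @export
ssc_threshold_sweep <- function(cells, channel,
                                thresholds = seq(0.4, 0.9, by = 0.05),
                                params = ssc_params()) {
  prof <- ssc_profile(cells, channel, params$fraction_mode)
  do.call(rbind, lapply(thresholds, function(th) {
    p <- params
    p$fraction_threshold <- th
    data.frame(threshold = th, cell_id = prof$cell_id,
               status = ssc_classify(prof, p))
  }))
}

#' Export an SSC result as CSV
#' @param ssc an `ssc_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ssc_result <- function(ssc, path) {
  tab <- ssc$table
  tab$marker <- ssc$marker
  write.csv(tab[, c("cell_id", "marker", "status", "mean_intensity",
                    "f1", "f2", "f3", "f4")], path, row.names = FALSE)
  invisible(path)
}
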