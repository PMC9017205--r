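# Channel image container, TIFF I/O, tile stitching and panel configuration.

#' One grayscale channel image
#'
#' A `channel_image` holds one 2-D grayscale intensity image for one marker at
#' one position (a tile or the stitched mosaic). Intensities are non-negative
#' on the nominal 16-bit export scale; images are assumed to be
#' background-subtracted upstream by the acquisition software, so no global
#' rescaling is ever applied.
#'
#' @param pixels numeric matrix of non-negative intensities, indexed
#'   `[row, col]` with origin top-left.
#' @param marker marker name (single string).
#' @param position_id tile identifier, or `"stitched"` for a mosaic.
#' @param pixel_origin `(row, col)` 0-based offset of this image within
#'   stitched coordinates.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, marker, position_id = "stitched",
                          pixel_origin = c(0L, 0L)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (anyNA(pixels) || any(pixels < 0))
    stop("channel intensities must be finite and >= 0")
  structure(list(pixels = pixels, marker = as.character(marker)[1],
                 position_id = as.character(position_id)[1],
                 pixel_origin = as.integer(pixel_origin)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> marker=%s position=%s %dx%d range=[%g, %g]\n",
              x$marker, x$position_id, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-plane grayscale TIFF channel
#'
#' Reads an 8- or 16-bit grayscale TIFF and returns the raw integer intensity
#' values unscaled. Multi-channel (e.g. RGB) images are rejected: the pipeline
#' operates on one grayscale image per marker.
#'
#' @param path path to the TIFF file.
#' @param marker marker name recorded on the returned image.
#' @param position_id position identifier; default is the file name without
#'   extension.
#' @return A [channel_image].
#' @export
read_channel <- function(path, marker, position_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read channel image: file '%s' does not exist", path))
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                 error = function(e)
                   stop(sprintf("failed to read '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  if (length(dim(px)) != 2L)
    stop(sprintf("'%s' is not a single-plane grayscale image (%d channels)",
                 path, dim(px)[3]))
  storage.mode(px) <- "double"
  channel_image(px, marker,
                position_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a channel image as a grayscale TIFF
#'
#' @param img a [channel_image].
#' @param path output path.
#' @param bits bits per sample (8 or 16). Values are rounded and clamped to
#'   the representable range; on read-back with [read_channel] integer values
#'   round-trip exactly.
#' @return `path`, invisibly.
#' @export
write_channel <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "channel_image"), bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  px <- pmin(pmax(round(img$pixels), 0), mx)
  tiff::writeTIFF(px / mx, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Tile-grid layout
#'
#' Describes how per-position tiles are laid out in the acquisition grid.
#' Tiles are placed at nominal grid positions (no cross-correlation
#' refinement); adjacent tiles overlap by `overlap_px` pixels.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param overlap_px expected overlap between adjacent tiles, in pixels.
#' @param order acquisition order: `"raster"` (row-major, always
#'   left-to-right) or `"serpentine"` (row-major, alternating direction).
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(n_rows, n_cols, overlap_px = 0L,
                      order = c("raster", "serpentine")) {
  order <- match.arg(order)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  overlap_px <- as.integer(overlap_px)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (overlap_px < 0L) stop("overlap_px must be >= 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, overlap_px = overlap_px,
                 order = order), class = "tile_grid")
}

# (row, col) grid position of the i-th tile in acquisition order.
grid_position <- function(grid, i) {
  r <- (i - 1L) %/% grid$n_cols + 1L
  c <- (i - 1L) %% grid$n_cols + 1L
  if (grid$order == "serpentine" && r %% 2L == 0L)
    c <- grid$n_cols - c + 1L
  c(r, c)
}

#' Stitch a tile grid into one image
#'
#' Tiles are placed at their nominal grid positions; in overlap zones the
#' per-pixel maximum of the contributing tiles is taken, which preserves
#' positive signals and is deterministic. The output shape is
#' `(n_rows*h - (n_rows-1)*overlap, n_cols*w - (n_cols-1)*overlap)`.
#'
#' @param tiles list of [channel_image] tiles in acquisition order; all must
#'   share shape and marker.
#' @param grid a [tile_grid]; `length(tiles)` must equal `n_rows * n_cols`.
#' @return A stitched [channel_image] with `position_id = "stitched"`.
#' @export
stitch_grid <- function(tiles, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tiles) != grid$n_rows * grid$n_cols)
    stop(sprintf("tile count mismatch: got %d tiles for a %dx%d grid",
                 length(tiles), grid$n_rows, grid$n_cols))
  h <- nrow(tiles[[1]]$pixels); w <- ncol(tiles[[1]]$pixels)
  marker <- tiles[[1]]$marker
  for (t in tiles) {
    if (nrow(t$pixels) != h || ncol(t$pixels) != w)
      stop("all tiles must have the same shape")
    if (t$marker != marker) stop("all tiles must belong to the same marker")
  }
  ov <- grid$overlap_px
  if (ov >= min(h, w)) stop("overlap_px must be smaller than the tile edge")
  H <- grid$n_rows * h - (grid$n_rows - 1L) * ov
  W <- grid$n_cols * w - (grid$n_cols - 1L) * ov
  out <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    rc <- grid_position(grid, i)
    r0 <- (rc[1] - 1L) * (h - ov)
    c0 <- (rc[2] - 1L) * (w - ov)
    rows <- (r0 + 1L):(r0 + h); cols <- (c0 + 1L):(c0 + w)
    out[rows, cols] <- pmax(out[rows, cols], tiles[[i]]$pixels)
  }
  channel_image(out, marker, "stitched")
}

#' Slice a stitched image back into a tile grid
#'
#' Inverse of [stitch_grid] at nominal positions: overlap strips are shared
#' between adjacent tiles, so re-stitching the slices reproduces the input
#' exactly.
#'
#' @param img stitched [channel_image].
#' @param grid a [tile_grid]; the stitched shape must be compatible.
#' @return List of [channel_image] tiles in acquisition order.
#' @export
slice_tiles <- function(img, grid) {
  H <- nrow(img$pixels); W <- ncol(img$pixels); ov <- grid$overlap_px
  h <- (H + (grid$n_rows - 1L) * ov) / grid$n_rows
  w <- (W + (grid$n_cols - 1L) * ov) / grid$n_cols
  if (h != floor(h) || w != floor(w))
    stop("stitched shape is not compatible with the tile grid")
  lapply(seq_len(grid$n_rows * grid$n_cols), function(i) {
    rc <- grid_position(grid, i)
    r0 <- (rc[1] - 1L) * (h - ov); c0 <- (rc[2] - 1L) * (w - ov)
    channel_image(img$pixels[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)],
                  img$marker, sprintf("%s_%d_%d", img$marker, rc[1], rc[2]),
                  pixel_origin = c(r0, c0))
  })
}

#' Panel configuration
#'
#' Maps marker names to their class and tile file pattern. Marker classes:
#' `nuclear` (nuclei or intranuclear stains, quantified on the raw channel),
#' `surface` (membrane stains, pre-processed and spillover-corrected) and
#' `structural` (tissue-architecture stains such as pan-cytokeratin).
#'
#' @param markers data.frame with columns `name` and `class`
#'   (`nuclear`/`surface`/`structural`).
#' @param nuclei_marker name of the (single) nuclei channel used for
#'   segmentation.
#' @param epithelial_marker name of the epithelial structural channel
#'   (pan-cytokeratin), or `NULL` when absent.
#' @param file_pattern sprintf-style pattern for tile files with placeholders
#'   marker, grid row, grid column.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(markers, nuclei_marker, epithelial_marker = NULL,
                         file_pattern = "%s_%d_%d.tif") {
  stopifnot(is.data.frame(markers), all(c("name", "class") %in% names(markers)))
  markers$name <- as.character(markers$name)
  markers$class <- as.character(markers$class)
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  if (!all(markers$class %in% c("nuclear", "surface", "structural")))
    stop("marker class must be one of nuclear, surface, structural")
  if (!nuclei_marker %in% markers$name)
    stop("nuclei_marker must be one of the panel markers")
  if (!is.null(epithelial_marker) && !epithelial_marker %in% markers$name)
    stop("epithelial_marker must be one of the panel markers")
  structure(list(markers = markers, nuclei_marker = nuclei_marker,
                 epithelial_marker = epithelial_marker,
                 file_pattern = file_pattern),
            class = "panel_config")
}

# File name of one tile.
tile_filename <- function(panel, marker, row, col) {
  sprintf(panel$file_pattern, marker, row, col)
}

# Marker class lookup.
marker_class <- function(panel, marker) {
  panel$markers$class[match(marker, panel$markers$name)]
}

#' Surface markers of a panel
#' @param panel a [panel_config].
#' @return Character vector of marker names with class `surface`.
#' @export
surface_markers <- function(panel) {
  panel$markers$name[panel$markers$class == "surface"]
}
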