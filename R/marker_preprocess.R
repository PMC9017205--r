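# Surface-marker pre-processing: speckle (outlier) removal and minimum
# filtering before quantification. Both filters use a digital disk
# neighbourhood (dy^2 + dx^2 <= radius^2, pixel included) with reflect
# padding at the image border.

#' Pre-processing parameters for surface channels
#'
#' Defaults: outlier radius 2 px with threshold 50 on the nominal 16-bit
#' export scale, minimum-filter radius 1 px. These remove sub-cellular
#' antibody-aggregate speckles without eroding membrane bands; all three are
#' recorded in the run log.
#'
#' @param outlier_radius disk radius of the outlier (conditional median)
#'   filter, pixels, >= 1.
#' @param outlier_threshold absolute deviation from the window median above
#'   which a pixel is replaced, intensity units, > 0.
#' @param min_filter_radius disk radius of the minimum filter (grayscale
#'   erosion), pixels, >= 1.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(outlier_radius = 2, outlier_threshold = 50,
                              min_filter_radius = 1) {
  if (outlier_radius < 1 || min_filter_radius < 1)
    stop("filter radii must be >= 1")
  if (outlier_threshold <= 0) stop("outlier_threshold must be > 0")
  structure(list(outlier_radius = outlier_radius,
                 outlier_threshold = outlier_threshold,
                 min_filter_radius = min_filter_radius),
            class = "preprocess_params")
}

#' Remove staining artefacts with an outlier filter
#'
#' Each pixel is compared with the median of its disk neighbourhood (pixel
#' included); if it deviates from that median by more than `threshold` it is
#' replaced by the median, otherwise left unchanged. A single pass reading
#' only from the input image. The deviation test is symmetric (bright and
#' dark outliers).
#'
#' @param img a [channel_image].
#' @param radius disk radius in pixels (>= 1).
#' @param threshold intensity deviation above which a pixel is replaced.
#' @return Filtered [channel_image].
#' @export
remove_outliers <- function(img, radius = 2, threshold = 50) {
  stopifnot(inherits(img, "channel_image"))
  if (radius < 1) stop("radius must be >= 1")
  med <- cpp_disk_median(img$pixels, radius)
  out <- img$pixels
  repl <- abs(out - med) > threshold
  out[repl] <- med[repl]
  channel_image(out, img$marker, img$position_id, img$pixel_origin)
}

#' Minimum filter (grayscale erosion)
#'
#' Replaces each pixel by the smallest value in its disk neighbourhood,
#' sharpening bright signals against blur towards neighbouring cells.
#'
#' @param img a [channel_image].
#' @param radius disk radius in pixels (>= 1).
#' @return Filtered [channel_image].
#' @export
min_filter <- function(img, radius = 1) {
  stopifnot(inherits(img, "channel_image"))
  if (radius < 1) stop("radius must be >= 1")
  channel_image(cpp_disk_min(img$pixels, radius), img$marker,
                img$position_id, img$pixel_origin)
}

#' Pre-process one channel according to its marker class
#'
#' Surface channels get the outlier filter followed by the minimum filter;
#' nuclear and structural channels pass through untouched.
#'
#' @param img a [channel_image].
#' @param class marker class (`nuclear`, `surface` or `structural`).
#' @param params a [preprocess_params].
#' @return The (possibly filtered) [channel_image].
#' @export
preprocess_channel <- function(img, class, params = preprocess_params()) {
  if (!identical(class, "surface")) return(img)
  img <- remove_outliers(img, params$outlier_radius, params$outlier_threshold)
  min_filter(img, params$min_filter_radius)
}
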