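# Nuclei segmentation with the cell-type-specific two-pass scheme:
# epithelial and non-epithelial cells are segmented separately by
# subtracting segmented crypts, each pass with its own particle filter.

#' Integer label map of segmented cells
#'
#' `labels` is an integer matrix the shape of the source image; 0 is
#' background and each positive value one cell ROI. Labels are mutually
#' disjoint by construction (a pixel belongs to at most one cell) and stay so
#' after every operation, including ROI enlargement. `compartment_of` tags
#' each label as `epithelial` or `non_epithelial`.
#'
#' @param labels integer matrix, values >= 0.
#' @param compartment_of named character vector mapping label id (as name) to
#'   compartment; labels missing from it default to `non_epithelial`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, compartment_of = NULL) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be >= 0")
  ids <- sort(unique(labels[labels > 0L]))
  comp <- setNames(rep("non_epithelial", length(ids)), as.character(ids))
  if (!is.null(compartment_of)) {
    keep <- intersect(names(compartment_of), names(comp))
    comp[keep] <- compartment_of[keep]
  }
  if (!all(comp %in% c("epithelial", "non_epithelial")))
    stop("compartment must be epithelial or non_epithelial")
  structure(list(labels = labels, compartment_of = comp), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %dx%d, %d cells (%d epithelial, %d non-epithelial)\n",
              nrow(x$labels), ncol(x$labels), length(x$compartment_of),
              sum(x$compartment_of == "epithelial"),
              sum(x$compartment_of == "non_epithelial")))
  invisible(x)
}

#' Number of cells in a label map
#' @param lm a [label_map].
#' @return Integer count of positive labels.
#' @export
n_cells <- function(lm) length(lm$compartment_of)

#' Compartment-specific particle filter parameters
#'
#' Area bounds are in pixels; circularity is `4*pi*area/perimeter^2`, clamped
#' to at most 1 on digital shapes.
#'
#' @param min_area_px,max_area_px inclusive pixel-area bounds, `0 <
#'   min_area_px <= max_area_px`.
#' @param min_circularity minimal circularity in `[0, 1]`.
#' @return An object of class `particle_params`.
#' @export
particle_params <- function(min_area_px, max_area_px, min_circularity) {
  if (min_area_px <= 0 || min_area_px > max_area_px)
    stop("need 0 < min_area_px <= max_area_px")
  if (min_circularity < 0 || min_circularity > 1)
    stop("min_circularity must be in [0, 1]")
  structure(list(min_area_px = min_area_px, max_area_px = max_area_px,
                 min_circularity = min_circularity), class = "particle_params")
}

#' @rdname particle_params
#' @details `epithelial_particle_params()` returns the epithelial defaults
#'   (size 75–2000 px, minimal circularity 0.2);
#'   `non_epithelial_particle_params()` the non-epithelial defaults (size
#'   70–400 px, minimal circularity 0.55).
#' @export
epithelial_particle_params <- function() particle_params(75, 2000, 0.2)

#' @rdname particle_params
#' @export
non_epithelial_particle_params <- function() particle_params(70, 400, 0.55)

#' Segmentation configuration
#'
#' Bundles all segmentation settings with the workflow defaults: Gaussian
#' blur sigma 1, automatic Otsu threshold (with optional fixed override for
#' stainings that do not fit the automatic threshold), watershed h-maxima
#' tolerance 1, both particle filters, 3-px ROI enlargement and the 1000-px
#' crypt-region minimum.
#'
#' @param sigma Gaussian blur sigma for the nuclei channel.
#' @param threshold_method `"otsu"`, `"yen"` or `"fixed"`.
#' @param fixed_threshold intensity threshold, required when
#'   `threshold_method = "fixed"`.
#' @param epithelial,non_epithelial [particle_params] per compartment.
#' @param enlarge_px ROI enlargement radius in pixels.
#' @param crypt_min_px minimal connected pan-cytokeratin region area.
#' @param watershed_h h-maxima suppression tolerance of the
#'   distance-transform watershed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(sigma = 1, threshold_method = "otsu",
                       fixed_threshold = NULL,
                       epithelial = epithelial_particle_params(),
                       non_epithelial = non_epithelial_particle_params(),
                       enlarge_px = 3, crypt_min_px = 1000, watershed_h = 1) {
  stopifnot(inherits(epithelial, "particle_params"),
            inherits(non_epithelial, "particle_params"))
  structure(list(sigma = sigma, threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, epithelial = epithelial,
                 non_epithelial = non_epithelial, enlarge_px = enlarge_px,
                 crypt_min_px = crypt_min_px, watershed_h = watershed_h),
            class = "seg_config")
}

#' Gaussian pre-smoothing of the nuclei channel
#'
#' @param img a [channel_image].
#' @param sigma blur width; 0 returns the image unchanged.
#' @return Smoothed [channel_image].
#' @export
preprocess_nuclei <- function(img, sigma = 1) {
  stopifnot(inherits(img, "channel_image"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  sm <- EBImage::imageData(EBImage::gblur(img$pixels, sigma = sigma))
  sm[sm < 0] <- 0  # FFT ringing can produce tiny negatives
  channel_image(sm, img$marker, img$position_id, img$pixel_origin)
}

# Yen's automatic threshold on an integer-binned histogram (entropic
# correlation criterion). Returns the bin value t such that the mask is
# pixels > t.
yen_threshold <- function(x, max_level = 65535L) {
  v <- pmin(pmax(floor(x), 0), max_level)
  counts <- tabulate(v + 1L, nbins = max_level + 1L)
  p <- counts / sum(counts)
  p2 <- p^2
  P1 <- cumsum(p)
  P1sq <- cumsum(p2)
  P2sq <- sum(p2) - P1sq
  n <- length(p)
  t <- seq_len(n - 1L)
  crit <- rep(-Inf, n - 1L)
  ok <- P1sq[t] > 0 & P2sq[t] > 0 & P1[t] > 0 & P1[t] < 1
  crit[ok] <- -log(P1sq[t[ok]] * P2sq[t[ok]]) +
    2 * log(P1[t[ok]] * (1 - P1[t[ok]]))
  (which.max(crit) - 1L)  # value of the last bin in the lower class
}

#' Threshold an image to a binary mask
#'
#' The mask is strictly `pixels > threshold`. Automatic methods: Otsu
#' (default for nuclei) or Yen's entropic criterion (used for the
#' pan-cytokeratin crypt mask). A fixed threshold mirrors the workflow's
#' manual override for stainings that do not fit the automatic parameters.
#'
#' @param img a [channel_image].
#' @param method `"otsu"`, `"yen"` or `"fixed"`.
#' @param fixed_threshold required if and only if `method = "fixed"`.
#' @return Logical matrix with attributes `threshold` and `method`.
#' @export
binarize <- function(img, method = c("otsu", "yen", "fixed"),
                     fixed_threshold = NULL) {
  stopifnot(inherits(img, "channel_image"))
  method <- match.arg(method)
  x <- img$pixels
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("fixed_threshold is required when method = 'fixed'")
    th <- fixed_threshold
  } else {
    if (diff(range(x)) == 0)
      stop("degenerate histogram (constant image): automatic thresholding ",
           "is undefined, use method = 'fixed' with an explicit threshold")
    th <- switch(method,
      otsu = {
        mx <- max(x)
        as.numeric(EBImage::otsu(EBImage::Image(x / mx), range = c(0, 1),
                                 levels = 65536L)) * mx
      },
      yen = yen_threshold(x))
  }
  mask <- x > th
  attr(mask, "threshold") <- as.numeric(th)
  attr(mask, "method") <- method
  mask
}

#' Split touching nuclei with a distance-transform watershed
#'
#' Runs the watershed on the Euclidean distance transform of the binary mask
#' with h-maxima suppression (tolerance `h`), so touching convex blobs are
#' split along distance ridges while single blobs stay whole.
#'
#' @param mask logical matrix from [binarize].
#' @param h watershed tolerance (h-maxima suppression depth).
#' @return A [label_map]; every label is a connected region.
#' @export
split_touching <- function(mask, h = 1) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(label_map(matrix(0L, nrow(mask), ncol(mask))))
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = h, ext = 1)
  label_map(matrix(as.integer(EBImage::imageData(w)), nrow(mask), ncol(mask)))
}

#' Filter particles on area and circularity
#'
#' Keeps labels with `min_area <= area <= max_area` and `circularity >=
#' min_circularity` (circularity clamped to at most 1). Removed labels are
#' reported with the reason in the `removed` attribute. Idempotent.
#'
#' @param lm a [label_map].
#' @param params a [particle_params].
#' @return Filtered [label_map] with attribute `removed`
#'   (data.frame: label, area, circularity, reason).
#' @export
filter_particles <- function(lm, params) {
  stopifnot(inherits(lm, "label_map"), inherits(params, "particle_params"))
  st <- label_stats(lm$labels)
  reason <- rep(NA_character_, nrow(st))
  reason[st$area < params$min_area_px] <- "area below minimum"
  reason[st$area > params$max_area_px] <- "area above maximum"
  low_circ <- is.na(reason) & st$circularity < params$min_circularity
  reason[low_circ] <- "circularity below minimum"
  drop <- st$label[!is.na(reason)]
  labels <- lm$labels
  labels[labels %in% drop] <- 0L
  out <- label_map(labels, lm$compartment_of)
  attr(out, "removed") <- data.frame(label = st$label[!is.na(reason)],
                                     area = st$area[!is.na(reason)],
                                     circularity = st$circularity[!is.na(reason)],
                                     reason = reason[!is.na(reason)])
  out
}

#' Epithelial (crypt) mask from the pan-cytokeratin channel
#'
#' Yen-thresholds the structural channel and keeps only connected regions of
#' at least `min_region_px` pixels (default 1000), i.e. crypt-scale
#' pan-cytokeratin positive areas.
#'
#' @param panck pan-cytokeratin [channel_image].
#' @param min_region_px minimal connected-region area in pixels.
#' @return Logical mask with attribute `threshold`.
#' @export
epithelial_mask <- function(panck, min_region_px = 1000) {
  mask <- binarize(panck, "yen")
  th <- attr(mask, "threshold")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_region_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  attr(mask, "threshold") <- th
  mask
}

# One segmentation pass: blur -> threshold -> watershed split -> particle
# filter, on an arbitrary template image.
segment_pass <- function(template, config, params) {
  sm <- preprocess_nuclei(template, config$sigma)
  mask <- binarize(sm, config$threshold_method, config$fixed_threshold)
  lm <- split_touching(mask, config$watershed_h)
  out <- filter_particles(lm, params)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Single-pass segmentation
#'
#' The conventional approach: one blur/threshold/watershed/filter chain over
#' the whole nuclei image with a single particle-filter setting (default the
#' wide epithelial parameters). Used as the baseline that the two-pass
#' cell-type-specific scheme is compared against.
#'
#' @param nuclei nuclei [channel_image].
#' @param config a [seg_config].
#' @param params [particle_params] for the single filter.
#' @return A [label_map] (all labels tagged `non_epithelial`).
#' @export
segment_cells_single <- function(nuclei, config = seg_config(),
                                 params = config$epithelial) {
  segment_pass(nuclei, config, params)
}

#' Cell-type-specific two-pass segmentation
#'
#' Epithelial and non-epithelial cells are segmented separately by
#' subtracting segmented crypts: (1) the Yen/1000-px crypt mask is zeroed out
#' of the nuclei channel and the remainder segmented with the strict
#' non-epithelial particle filter; (2) the footprints of the step-1 cells are
#' zeroed out of the original nuclei image and the remainder segmented with
#' the wide epithelial filter. Each pass computes its own automatic
#' threshold, which is what recovers compartments whose nuclei staining
#' differs in intensity or packing. The union is returned with disjoint
#' renumbered labels and a compartment tag per label. Without a
#' pan-cytokeratin channel the function falls back to single-pass
#' segmentation with the epithelial (wide) parameters.
#'
#' @param nuclei nuclei [channel_image].
#' @param panck pan-cytokeratin [channel_image], or `NULL` when absent.
#' @param config a [seg_config].
#' @return A [label_map]; attribute `thresholds` records the per-pass
#'   thresholds in the run log.
#' @export
segment_cells_by_type <- function(nuclei, panck = NULL,
                                  config = seg_config()) {
  stopifnot(inherits(nuclei, "channel_image"))
  if (is.null(panck)) {
    out <- segment_cells_single(nuclei, config, config$epithelial)
    attr(out, "thresholds") <- c(single = attr(out, "threshold"))
    return(out)
  }
  emask <- epithelial_mask(panck, config$crypt_min_px)

  t1 <- nuclei$pixels
  t1[emask] <- 0
  pass1 <- segment_pass(channel_image(t1, nuclei$marker), config,
                        config$non_epithelial)

  t2 <- nuclei$pixels
  t2[pass1$labels > 0L] <- 0
  pass2 <- segment_pass(channel_image(t2, nuclei$marker), config,
                        config$epithelial)

  lab1 <- pass1$labels
  lab2 <- pass2$labels
  # safety: blur can bleed across the zeroed footprints; never let a pass-2
  # label overlap a pass-1 cell
  lab2[lab1 > 0L] <- 0L

  ids1 <- sort(unique(lab1[lab1 > 0L]))
  ids2 <- sort(unique(lab2[lab2 > 0L]))
  n1 <- length(ids1)
  relab1 <- integer(max(lab1, 1L)); relab1[ids1] <- seq_len(n1)
  relab2 <- integer(max(lab2, 1L)); relab2[ids2] <- n1 + seq_along(ids2)
  out <- matrix(0L, nrow(lab1), ncol(lab1))
  out[lab1 > 0L] <- relab1[lab1[lab1 > 0L]]
  out[lab2 > 0L] <- relab2[lab2[lab2 > 0L]]
  if (any(out[lab1 > 0L] != relab1[lab1[lab1 > 0L]]))
    stop("internal consistency error: overlapping labels after union")

  comp <- c(setNames(rep("non_epithelial", n1), as.character(seq_len(n1))),
            setNames(rep("epithelial", length(ids2)),
                     as.character(n1 + seq_along(ids2))))
  res <- label_map(out, comp)
  attr(res, "thresholds") <- c(non_epithelial = attr(pass1, "threshold"),
                               epithelial = attr(pass2, "threshold"))
  attr(res, "epithelial_mask_px") <- sum(emask)
  res
}

#' Enlarge ROIs by a fixed radius
#'
#' Each label is dilated by a disk of radius `by_px` (default 3) to cover the
#' surface signal around the nucleus. Collisions are resolved by
#' nearest-seed assignment: every contested pixel goes to the label whose
#' original ROI is closest (Euclidean distance), ties to the lower label id,
#' so labels remain mutually disjoint.
#'
#' @param lm a [label_map].
#' @param by_px enlargement radius in pixels, >= 0.
#' @return Enlarged [label_map].
#' @export
enlarge_rois <- function(lm, by_px = 3) {
  stopifnot(inherits(lm, "label_map"))
  if (by_px < 0) stop("by_px must be >= 0")
  if (by_px == 0 || n_cells(lm) == 0L) return(lm)
  labels <- lm$labels
  n <- nrow(labels); m <- ncol(labels)
  best_dist <- matrix(Inf, n, m)
  best_lab <- matrix(0L, n, m)
  pix <- label_index(labels)
  pad <- as.integer(ceiling(by_px)) + 1L
  for (id_chr in names(pix)) {
    id <- as.integer(id_chr)
    rc <- idx_rc(pix[[id_chr]], n)
    r0 <- max(1L, min(rc[, "row"]) - pad); r1 <- min(n, max(rc[, "row"]) + pad)
    c0 <- max(1L, min(rc[, "col"]) - pad); c1 <- min(m, max(rc[, "col"]) + pad)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rc[, "row"] - r0 + 1L, rc[, "col"] - c0 + 1L)] <- 1
    # distance of every crop pixel to this label's ROI
    d <- EBImage::imageData(EBImage::distmap(1 - sub))
    rows <- r0:r1; cols <- c0:c1
    win_dist <- best_dist[rows, cols]
    win_lab <- best_lab[rows, cols]
    upd <- d < win_dist - 1e-9  # strict improvement: ties keep lower label
    win_dist[upd] <- d[upd]
    win_lab[upd] <- id
    best_dist[rows, cols] <- win_dist
    best_lab[rows, cols] <- win_lab
  }
  grow <- labels == 0L & best_dist <= by_px + 1e-9
  out <- labels
  out[grow] <- best_lab[grow]
  label_map(out, lm$compartment_of)
}

#' Serialize a label map
#'
#' Writes the labels as a 16-bit grayscale TIFF (exact for up to 65535
#' labels) plus a CSV sidecar with the label-to-compartment table.
#'
#' @param lm a [label_map].
#' @param path output TIFF path; the sidecar gets the same name with
#'   extension `.csv`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  if (max(lm$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L)
  side <- paste0(tools::file_path_sans_ext(path), ".csv")
  write.csv(data.frame(label = as.integer(names(lm$compartment_of)),
                       compartment = unname(lm$compartment_of)),
            side, row.names = FALSE)
  invisible(path)
}

#' Read a serialized label map
#' @param path TIFF path written by [write_label_map].
#' @return A [label_map].
#' @export
read_label_map <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  side <- paste0(tools::file_path_sans_ext(path), ".csv")
  comp <- NULL
  if (file.exists(side)) {
    tab <- read.csv(side)
    comp <- setNames(as.character(tab$compartment), as.character(tab$label))
  }
  label_map(matrix(as.integer(px), nrow(px), ncol(px)), comp)
}
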