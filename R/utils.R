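# Internal helpers shared across modules.
#
# Coordinate convention (used everywhere): images are matrices indexed
# [row, col], origin top-left. Exported x/y coordinates are 0-based
# (x = col - 1, y = row - 1); internal R indexing is 1-based.

# Integer offsets (dy, dx) of a digital disk: dy^2 + dx^2 <= radius^2.
disk_offsets <- function(radius) {
  k <- as.integer(floor(radius))
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# Row/col coordinates of linear indices in an n-row matrix.
idx_rc <- function(idx, n) {
  cbind(row = ((idx - 1L) %% n) + 1L, col = ((idx - 1L) %/% n) + 1L)
}

# Pixel linear indices per positive label, as a named list ("1", "2", ...).
label_index <- function(labels) {
  fg <- which(labels > 0L)
  split(fg, labels[fg])
}

# Boundary length of a binary blob from its marching-squares iso-contour at
# level 0.5 (sub-pixel linear interpolation). Robust for arbitrary blobs;
# degenerate very small blobs are handled by the circularity convention below.
perimeter_contour <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  z <- matrix(0, n + 2L, m + 2L)
  z[2:(n + 1L), 2:(m + 1L)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(n + 2L), y = seq_len(m + 2L),
                                z = z, levels = 0.5)
  total <- 0
  for (ct in cl) {
    x <- ct$x; y <- ct$y
    total <- total + sum(sqrt(diff(x)^2 + diff(y)^2))
    # close the loop if the contour is returned open
    total <- total + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  }
  total
}

# Circularity 4*pi*A/P^2, clamped to (0, 1]. On digital shapes the raw value
# can exceed 1 (discretised perimeter underestimates), hence the clamp. Blobs
# of < 5 px are too small for a meaningful contour and count as round.
blob_circularity <- function(mask) {
  a <- sum(mask)
  if (a < 5L) return(1)
  p <- perimeter_contour(mask)
  if (p <= 0) return(1)
  min(1, 4 * pi * a / p^2)
}

# Per-label area, centroid and circularity.
# Returns a data.frame(label, area, row, col, circularity).
label_stats <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(), area = integer(), row = numeric(),
                      col = numeric(), circularity = numeric()))
  }
  n <- nrow(labels)
  pix <- label_index(labels)
  out <- data.frame(label = ids, area = NA_integer_, row = NA_real_,
                    col = NA_real_, circularity = NA_real_)
  for (i in seq_along(ids)) {
    idx <- pix[[as.character(ids[i])]]
    rc <- idx_rc(idx, n)
    out$area[i] <- length(idx)
    out$row[i] <- mean(rc[, "row"])
    out$col[i] <- mean(rc[, "col"])
    r0 <- range(rc[, "row"]); c0 <- range(rc[, "col"])
    sub <- matrix(FALSE, r0[2] - r0[1] + 1L, c0[2] - c0[1] + 1L)
    sub[cbind(rc[, "row"] - r0[1] + 1L, rc[, "col"] - c0[1] + 1L)] <- TRUE
    out$circularity[i] <- blob_circularity(sub)
  }
  out
}

# Filled-ellipse pixel mask (linear indices) for a cell.
# theta: orientation of the first semi-axis, radians, counter-clockwise in
# (row, col) space.
ellipse_indices <- function(row0, col0, a, b, theta, shape) {
  rmax <- ceiling(max(a, b))
  rows <- max(1L, floor(row0 - rmax)):min(shape[1], ceiling(row0 + rmax))
  cols <- max(1L, floor(col0 - rmax)):min(shape[2], ceiling(col0 + rmax))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - row0; dx <- g$col - col0
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (g$col[keep] - 1L) * shape[1] + g$row[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
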