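# Independent brute-force oracles. These deliberately share no code with the
# package implementations beyond the stated conventions (disk neighbourhood
# dy^2+dx^2 <= r^2, symmetric reflect padding, strict > thresholds).

reflect_ref <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

# per-pixel windowed median over a disk, reflect padding
oracle_disk_median <- function(x, radius) {
  n <- nrow(x); m <- ncol(x)
  k <- floor(radius)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    for (dy in -k:k) for (dx in -k:k) {
      if (dy^2 + dx^2 <= radius^2 + 1e-9)
        vals <- c(vals, x[reflect_ref(i + dy, n), reflect_ref(j + dx, m)])
    }
    out[i, j] <- median(vals)
  }
  out
}

oracle_remove_outliers <- function(x, radius, threshold) {
  med <- oracle_disk_median(x, radius)
  ifelse(abs(x - med) > threshold, med, x)
}

oracle_min_filter <- function(x, radius) {
  n <- nrow(x); m <- ncol(x)
  k <- floor(radius)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    mn <- Inf
    for (dy in -k:k) for (dx in -k:k) {
      if (dy^2 + dx^2 <= radius^2 + 1e-9)
        mn <- min(mn, x[reflect_ref(i + dy, n), reflect_ref(j + dx, m)])
    }
    out[i, j] <- mn
  }
  out
}

# nominal-grid tile placement with per-pixel maximum, raster order
oracle_stitch <- function(mats, n_rows, n_cols, ov) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  H <- n_rows * h - (n_rows - 1) * ov
  W <- n_cols * w - (n_cols - 1) * ov
  out <- matrix(0, H, W)
  for (i in seq_along(mats)) {
    r <- (i - 1) %/% n_cols; c <- (i - 1) %% n_cols
    for (a in seq_len(h)) for (b in seq_len(w)) {
      ra <- r * (h - ov) + a; cb <- c * (w - ov) + b
      out[ra, cb] <- max(out[ra, cb], mats[[i]][a, b])
    }
  }
  out
}

# Yen's criterion computed from scratch (no cumulative sums) for one cut:
# maximise over candidate cuts; returns the binary mask of the best cut.
oracle_yen_mask <- function(x, levels = 0:255) {
  v <- as.vector(x)
  p <- vapply(levels, function(l) mean(v == l), numeric(1))
  best <- -Inf; best_t <- NA
  for (ti in seq_along(levels)[-length(levels)]) {
    P1 <- sum(p[1:ti]); P1sq <- sum(p[1:ti]^2)
    P2sq <- sum(p[(ti + 1):length(p)]^2)
    if (P1 <= 0 || P1 >= 1 || P1sq <= 0 || P2sq <= 0) next
    crit <- -log(P1sq * P2sq) + 2 * log(P1 * (1 - P1))
    if (crit > best) { best <- crit; best_t <- levels[ti] }
  }
  list(mask = x > best_t, threshold = best_t, criterion = best)
}

# 4-direction Crofton perimeter estimate from directional intercept counts
oracle_crofton_perimeter <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  trans <- function(shift_r, shift_c) {
    a <- pad[1:(n + 1), 1:(m + 1)]
    b <- pad[1:(n + 1) + shift_r, 1:(m + 1) + shift_c]
    sum(a != b)
  }
  n0 <- trans(0, 1); n90 <- trans(1, 0)
  n45 <- trans(1, 1); n135 <- {
    a <- pad[2:(n + 2), 1:(m + 1)]
    b <- pad[1:(n + 1), 2:(m + 2)]
    sum(a != b)
  }
  # Cauchy-Crofton with 4 directions: each boundary crossing is seen from
  # both sides of the transition, hence the factor pi/8
  pi / 8 * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# per-pixel quadrant classification + signal sums for one ROI
oracle_quadrant_fractions <- function(img, roi, centroid = NULL) {
  idx <- which(roi, arr.ind = TRUE)
  if (is.null(centroid)) centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  sums <- numeric(4)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    q <- if (r < centroid[1] && c < centroid[2]) 1
    else if (r < centroid[1]) 2
    else if (c < centroid[2]) 3
    else 4
    sums[q] <- sums[q] + img[r, c]
  }
  if (sum(sums) <= 0) rep(0.25, 4) else sums / sum(sums)
}

# direct dense convolution with a normalised Gaussian kernel (circular
# boundary, matching the FFT convolution used for nuclei smoothing)
oracle_gaussian_center_response <- function(sigma) {
  size <- 2 * ceiling(3 * sigma) + 1
  half <- (size - 1) / 2
  g <- outer(-half:half, -half:half,
             function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

# independent byte-level FCS parse: header offsets by fixed position, raw
# little-endian float reads; no shared code with read_fcs
oracle_read_fcs_bytes <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  hdr <- rawToChar(raw[1:58])
  stopifnot(substr(hdr, 1, 6) == "FCS3.1")
  text_begin <- as.integer(substr(hdr, 11, 18))
  text_end <- as.integer(substr(hdr, 19, 26))
  data_begin <- as.integer(substr(hdr, 27, 34))
  txt <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  d <- substr(txt, 1, 1)
  kv <- strsplit(substring(txt, 2), d, fixed = TRUE)[[1]]
  keys <- kv[seq(1, length(kv) - 1, 2)]
  vals <- kv[seq(2, length(kv), 2)]
  names(vals) <- keys
  n <- as.integer(vals["$TOT"]); p <- as.integer(vals["$PAR"])
  mat <- matrix(readBin(raw[(data_begin + 1):length(raw)], "numeric",
                        n = n * p, size = 4, endian = "little"),
                nrow = n, byrow = TRUE)
  colnames(mat) <- unname(vals[sprintf("$P%dN", seq_len(p))])
  list(data = mat, keywords = vals)
}

# helper: random integer test image
rand_img <- function(n = 32, m = 32, max_val = 255) {
  matrix(sample(0:max_val, n * m, replace = TRUE), n, m)
}

as_ci <- function(m, marker = "t") channel_image(m, marker)
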