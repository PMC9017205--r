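# Synthetic multiplexed tissue scenes with full ground truth: crypt-like
# epithelium, membrane-stained immune cells, mutually exclusive marker
# pairs, contact spillover artefacts and antibody-aggregate speckles.
#
# The generator's defaults define the conditions the test suite and the
# acceptance checks run under; see the methods vignette for the rationale
# behind each default.

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Demonstration marker panel
#'
#' An 11-channel colon-immune panel: Hoechst-like nuclei channel (`DNA`),
#' pan-cytokeratin (`panCK`, structural, defines the epithelial
#' compartment), and surface/intranuclear immune and architecture markers.
#' `CD4` and `CD8` are the canonical mutually exclusive pair.
#'
#' @return A [panel_config].
#' @export
demo_panel <- function() {
  markers <- data.frame(
    name  = c("DNA", "panCK", "ECad", "Vimentin", "SMA", "CD45", "CD3",
              "CD4", "CD8", "CD45RO", "Foxp3"),
    class = c("nuclear", "structural", "surface", "surface", "surface",
              "surface", "surface", "surface", "surface", "surface",
              "nuclear"))
  panel_config(markers, nuclei_marker = "DNA", epithelial_marker = "panCK")
}

#' Generate a synthetic tissue scene
#'
#' Lays out elliptical cells in two compartments — epithelial cells packed
#' inside crypt-like elliptical annuli, non-epithelial (stromal/immune)
#' cells filling the remaining tissue more densely — assigns ground-truth
#' marker positivity with an immune-lineage hierarchy, and draws spillover
#' artefacts (bright contact aggregates from positive cells onto adjacent
#' negative cells) and free antibody-aggregate speckles. Fully reproducible
#' for a fixed seed.
#'
#' Marker-positive membranes may be partially stained ("capped"): a fraction
#' of positive cells carries signal on only an arc of the membrane, which is
#' what makes aggressive spillover thresholds delete real cells.
#'
#' Spillover acceptance is coupled across rates: for a fixed seed, the edge
#' set at a lower rate is a subset of the edge set at a higher rate, so the
#' double-positive artefact burden is monotone in `spillover_rate` by
#' construction.
#'
#' @param shape image shape `(rows, cols)`.
#' @param density expected cells per 10,000 px^2 (0 gives an empty scene).
#' @param epithelial_fraction fraction of cells that are epithelial.
#' @param exclusive_pairs list of length-2 character vectors of mutually
#'   exclusive markers; never co-assigned to one cell.
#' @param spillover_rate per (positive source, adjacent negative neighbour)
#'   probability of a spillover artefact. Victims that are positive for the
#'   exclusive partner of the spilling marker are `partner_affinity` times
#'   more likely to be hit (immune cells of related lineages sit next to
#'   each other in an infiltrate).
#' @param speckle_rate expected antibody-aggregate speckles per surface
#'   channel per 512x512 area.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @param panel a [panel_config]; markers referenced by the lineage rules
#'   must exist in it.
#' @param partner_affinity spillover preference for exclusive-partner
#'   victims (see `spillover_rate`).
#' @param capped_prob probability that a positive membrane is only partially
#'   stained.
#' @return An object of class `synth_scene`.
#' @export
make_scene <- function(shape = c(896L, 896L), density = 8,
                       epithelial_fraction = 0.35,
                       exclusive_pairs = list(c("CD4", "CD8")),
                       spillover_rate = 0.15, speckle_rate = 6,
                       seed = 1L, panel = demo_panel(),
                       partner_affinity = 7, capped_prob = 0.25) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 64L), density >= 0,
            epithelial_fraction >= 0, epithelial_fraction <= 1,
            spillover_rate >= 0, spillover_rate <= 1)
  with_seed(seed, {
    n_total <- round(density * prod(shape) / 1e4)
    n_epi <- round(epithelial_fraction * n_total)
    n_non <- n_total - n_epi
    margin <- 12

    # ---- crypts (only when epithelial cells are requested) ----
    crypts <- data.frame(row = numeric(), col = numeric(), a_out = numeric(),
                         b_out = numeric(), theta = numeric(),
                         thickness = numeric())
    if (n_epi > 0L) {
      s_min <- min(shape)
      # enough crypts for the tissue area and for the epithelial demand
      n_crypts <- max(1L, round(prod(shape) / 2e5), ceiling(n_epi / 40))
      for (k in seq_len(n_crypts)) {
        for (att in seq_len(200)) {
          a_out <- runif(1, min(70, s_min / 6), min(95, s_min / 4.5))
          b_out <- a_out * runif(1, 0.85, 1)
          th <- runif(1, 0, pi)
          r0 <- runif(1, a_out + margin, shape[1] - a_out - margin)
          c0 <- runif(1, a_out + margin, shape[2] - a_out - margin)
          ok <- TRUE
          if (nrow(crypts) > 0) {
            d <- sqrt((crypts$row - r0)^2 + (crypts$col - c0)^2)
            ok <- all(d > crypts$a_out + a_out + 24)
          }
          if (ok) {
            crypts <- rbind(crypts, data.frame(
              row = r0, col = c0, a_out = a_out, b_out = b_out, theta = th,
              thickness = a_out * runif(1, 0.26, 0.30)))
            break
          }
        }
      }
    }

    # ---- cell placement (rejection sampling on centres) ----
    cells <- data.frame(id = integer(), row = numeric(), col = numeric(),
                        a = numeric(), b = numeric(), theta = numeric(),
                        compartment = character())
    place <- function(row0, col0, a, b, comp, spacing) {
      if (nrow(cells) > 0) {
        g <- sqrt(cells$a * cells$b)
        d <- sqrt((cells$row - row0)^2 + (cells$col - col0)^2)
        if (any(d < spacing * (g + sqrt(a * b)))) return(FALSE)
      }
      cells[nrow(cells) + 1L, ] <<- list(nrow(cells) + 1L, row0, col0, a, b,
                                         runif(1, 0, pi), comp)
      TRUE
    }
    # epithelial: along the crypt annulus mid-band, tightly packed
    placed_epi <- 0L
    if (n_epi > 0L && nrow(crypts) > 0L) {
      circ <- 2 * pi * sqrt(crypts$a_out * crypts$b_out)
      for (i in seq_len(n_epi)) {
        done <- FALSE
        for (att in seq_len(300)) {
          k <- sample.int(nrow(crypts), 1L, prob = circ)
          cr <- crypts[k, ]
          phi <- runif(1, 0, 2 * pi)
          u <- runif(1, 0.12, 0.88)  # radial position inside the band
          a_eff <- cr$a_out - cr$thickness * (1 - u)
          b_eff <- cr$b_out - cr$thickness * (1 - u)
          dy <- a_eff * cos(phi) * sin(cr$theta) + b_eff * sin(phi) * cos(cr$theta)
          dx <- a_eff * cos(phi) * cos(cr$theta) - b_eff * sin(phi) * sin(cr$theta)
          a <- runif(1, 5.8, 7.5); b <- a * runif(1, 0.85, 1)
          r0 <- cr$row + dy; c0 <- cr$col + dx
          if (r0 < margin || c0 < margin || r0 > shape[1] - margin ||
              c0 > shape[2] - margin) next
          if (place(r0, c0, a, b, "epithelial", 0.92)) { done <- TRUE; break }
        }
        if (done) placed_epi <- placed_epi + 1L
      }
      if (placed_epi < 0.8 * n_epi)
        stop(sprintf(paste0("unreachable density: placed %d of %d epithelial",
                            " cells (achieved density %.2f per 1e4 px^2)"),
                     placed_epi, n_epi,
                     (placed_epi + n_non) * 1e4 / prod(shape)))
    }
    # non-epithelial: clustered infiltrate foci outside the crypts — dense
    # local packing is what creates cell-cell contacts and hence spillover
    placed_non <- 0L
    if (n_non > 0L) {
      in_crypt <- function(r0, c0) {
        if (nrow(crypts) == 0L) return(FALSE)
        dy <- r0 - crypts$row; dx <- c0 - crypts$col
        u <- dx * cos(crypts$theta) + dy * sin(crypts$theta)
        v <- -dx * sin(crypts$theta) + dy * cos(crypts$theta)
        any((u / (crypts$a_out + 4))^2 + (v / (crypts$b_out + 4))^2 <= 1)
      }
      n_foci <- max(1L, round(n_non / 30))
      foci <- matrix(NA_real_, n_foci, 2)
      k <- 0L
      for (att in seq_len(500)) {
        if (k >= n_foci) break
        r0 <- runif(1, margin + 20, shape[1] - margin - 20)
        c0 <- runif(1, margin + 20, shape[2] - margin - 20)
        if (!in_crypt(r0, c0)) { k <- k + 1L; foci[k, ] <- c(r0, c0) }
      }
      foci <- foci[seq_len(k), , drop = FALSE]
      for (i in seq_len(n_non)) {
        for (att in seq_len(300)) {
          f <- foci[sample.int(nrow(foci), 1L), ]
          r0 <- rnorm(1, f[1], 22); c0 <- rnorm(1, f[2], 22)
          if (r0 < margin || c0 < margin || r0 > shape[1] - margin ||
              c0 > shape[2] - margin) next
          if (in_crypt(r0, c0)) next
          a <- runif(1, 5.6, 7.0); b <- a * runif(1, 0.85, 1)
          if (place(r0, c0, a, b, "non_epithelial", 0.95)) {
            placed_non <- placed_non + 1L
            break
          }
        }
      }
      if (placed_non < 0.8 * n_non)
        stop(sprintf(paste0("unreachable density: placed %d of %d",
                            " non-epithelial cells (achieved density %.2f",
                            " per 1e4 px^2)"),
                     placed_non, n_non,
                     (placed_epi + placed_non) * 1e4 / prod(shape)))
    }
    n <- nrow(cells)

    # ---- ground-truth marker assignment ----
    mk <- panel$markers$name
    truth <- matrix(FALSE, n, length(mk), dimnames = list(NULL, mk))
    if (n > 0L) {
      truth[, panel$nuclei_marker] <- TRUE
      epi <- cells$compartment == "epithelial"
      if (!is.null(panel$epithelial_marker))
        truth[, panel$epithelial_marker] <- epi
      has <- function(m) m %in% mk
      if (has("ECad")) truth[, "ECad"] <- epi
      if (has("Vimentin")) truth[, "Vimentin"] <- !epi
      cd45 <- !epi & runif(n) < 0.85
      if (has("CD45")) truth[, "CD45"] <- cd45
      if (has("SMA")) truth[, "SMA"] <- !epi & !cd45
      cd3 <- cd45 & runif(n) < 0.8
      if (has("CD3")) truth[, "CD3"] <- cd3
      is_cd4 <- runif(n) < 0.62
      if (has("CD4")) truth[, "CD4"] <- cd3 & is_cd4
      if (has("CD8")) truth[, "CD8"] <- cd3 & !is_cd4
      if (has("Foxp3") && has("CD4"))
        truth[, "Foxp3"] <- truth[, "CD4"] & runif(n) < 0.12
      if (has("CD45RO")) truth[, "CD45RO"] <- cd45 & runif(n) < 0.45
      # enforce declared exclusivity whatever the lineage rules did
      for (pr in exclusive_pairs) {
        if (!all(pr %in% mk)) next
        both <- truth[, pr[1]] & truth[, pr[2]]
        drop_first <- runif(n) < 0.5
        truth[both & drop_first, pr[1]] <- FALSE
        truth[both & !drop_first, pr[2]] <- FALSE
      }
    }

    # ---- capped (partial) membrane staining ----
    surf <- surface_markers(panel)
    coverage <- matrix(1, n, length(surf), dimnames = list(NULL, surf))
    phase <- matrix(0, n, length(surf), dimnames = list(NULL, surf))
    if (n > 0L) for (m in surf) {
      pos <- which(truth[, m])
      for (i in pos) {
        if (runif(1) < capped_prob) coverage[i, m] <- runif(1, 0.65, 1)
        phase[i, m] <- runif(1, 0, 2 * pi)
      }
    }

    # ---- spillover edges (one per victim and marker, strongest kept) ----
    partner <- character(0)
    for (pr in exclusive_pairs) {
      partner[pr[1]] <- pr[2]; partner[pr[2]] <- pr[1]
    }
    edges <- data.frame(source = integer(), victim = integer(),
                        marker = character(), strength = numeric())
    if (n > 1L) {
      g <- sqrt(cells$a * cells$b)
      d <- as.matrix(stats::dist(cells[, c("row", "col")]))
      adj <- which(d > 0 & d < outer(g, g, "+") + 8, arr.ind = TRUE)
      adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
      adj <- adj[order(adj[, 1], adj[, 2]), , drop = FALSE]
      for (m in surf) {
        for (k in seq_len(nrow(adj))) {
          s <- adj[k, 1]; v <- adj[k, 2]
          # deterministic candidate order; draws consumed for every
          # candidate so that scenes are comparable across rates
          u <- runif(1); strength <- runif(1, 0.75, 0.98)
          if (!truth[s, m] || truth[v, m]) next
          w <- if (!is.na(partner[m]) && truth[v, partner[m]])
            partner_affinity else 1
          if (u < min(1, spillover_rate * w)) {
            prev <- which(edges$victim == v & edges$marker == m)
            if (length(prev) == 0L) {
              edges[nrow(edges) + 1L, ] <- list(s, v, m, strength)
            } else if (strength > edges$strength[prev]) {
              edges[prev, ] <- list(s, v, m, strength)
            }
          }
        }
      }
    }

    # ---- speckles ----
    speckles <- data.frame(row = numeric(), col = numeric(),
                           radius = numeric(), intensity = numeric(),
                           marker = character())
    for (m in surf) {
      k <- rpois(1, speckle_rate * prod(shape) / 512^2)
      if (k > 0L) {
        speckles <- rbind(speckles, data.frame(
          row = runif(k, 4, shape[1] - 4), col = runif(k, 4, shape[2] - 4),
          radius = 1, intensity = runif(k, 3000, 6000), marker = m))
      }
    }

    structure(list(
      shape = shape, cells = cells, crypts = crypts, marker_truth = truth,
      coverage = coverage, coverage_phase = phase, spillover_edges = edges,
      speckles = speckles, exclusive_pairs = exclusive_pairs, panel = panel,
      params = list(density = density, epithelial_fraction = epithelial_fraction,
                    spillover_rate = spillover_rate,
                    partner_affinity = partner_affinity,
                    capped_prob = capped_prob, speckle_rate = speckle_rate,
                    seed = seed)),
      class = "synth_scene")
  })
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf(paste0("<synth_scene> %dx%d px, %d cells (%d epithelial),",
                     " %d spillover edges, %d speckles, seed %d\n"),
              x$shape[1], x$shape[2], nrow(x$cells),
              sum(x$cells$compartment == "epithelial"),
              nrow(x$spillover_edges), nrow(x$speckles), x$params$seed))
  invisible(x)
}

#' Render a scene into per-marker channel images
#'
#' Channel model (all intensities on the nominal 16-bit export scale):
#' nuclei are filled ellipses (foreground 1000 for non-epithelial,
#' 300 for epithelial nuclei — dim, densely packed crypt nuclei are what
#' motivates the separate segmentation); pan-cytokeratin fills the crypt
#' annuli; each surface marker paints a 4-px membrane band on its positive
#' cells, restricted to the stained arc for capped cells; intranuclear
#' markers fill the nucleus. Every spillover edge adds a bright aggregate
#' blob on the victim boundary facing the source; speckles are 1-px-radius
#' aggregates. Channels share shape, and get additive truncated-Gaussian
#' background noise (clipped at 0) on a constant low-level background.
#'
#' @param scene a [synth_scene].
#' @param panel panel to render (default the scene's).
#' @param foreground nominal foreground intensity.
#' @param background constant residual background level.
#' @param noise_sd additive Gaussian noise sd (default 2% of foreground).
#' @param epithelial_nuclei_factor intensity factor of epithelial nuclei.
#' @param band_px membrane band thickness in pixels.
#' @param aggregate_intensity nominal intensity of spillover aggregates;
#'   each blob is drawn at `strength * aggregate_intensity`.
#' @param blob_radius spillover aggregate radius in pixels.
#' @param seed RNG seed of the noise draw (default derived from the scene
#'   seed, so rendering is reproducible end-to-end).
#' @return Named list of [channel_image], one per panel marker.
#' @export
render_scene <- function(scene, panel = scene$panel, foreground = 1000,
                         background = 10, noise_sd = 20,
                         epithelial_nuclei_factor = 0.3, band_px = 5,
                         aggregate_intensity = 9500, blob_radius = 3.6,
                         seed = scene$params$seed + 10000L) {
  stopifnot(inherits(scene, "synth_scene"))
  shape <- scene$shape
  cells <- scene$cells
  n <- nrow(cells)
  blank <- function() matrix(0, shape[1], shape[2])

  foot <- lapply(seq_len(n), function(i)
    ellipse_indices(cells$row[i], cells$col[i], cells$a[i], cells$b[i],
                    cells$theta[i], shape))
  band <- lapply(seq_len(n), function(i) {
    a2 <- cells$a[i] - band_px; b2 <- cells$b[i] - band_px
    if (a2 <= 0.5 || b2 <= 0.5) return(foot[[i]])
    setdiff(foot[[i]], ellipse_indices(cells$row[i], cells$col[i], a2, b2,
                                       cells$theta[i], shape))
  })

  arc_subset <- function(i, idx, m) {
    cov <- scene$coverage[i, m]
    if (cov >= 1) return(idx)
    rc <- idx_rc(idx, shape[1])
    ang <- atan2(rc[, "row"] - cells$row[i], rc[, "col"] - cells$col[i])
    idx[((ang - scene$coverage_phase[i, m]) %% (2 * pi)) <= cov * 2 * pi]
  }

  disk_at <- function(r0, c0, radius) {
    off <- disk_offsets(radius)
    r <- round(r0) + off$dy; c <- round(c0) + off$dx
    keep <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
    (c[keep] - 1L) * shape[1] + r[keep]
  }

  out <- list()
  for (m in panel$markers$name) {
    cls <- marker_class(panel, m)
    img <- blank()
    if (n > 0L) {
      if (m == panel$nuclei_marker) {
        for (i in seq_len(n)) {
          val <- foreground *
            if (cells$compartment[i] == "epithelial")
              epithelial_nuclei_factor else 1
          img[foot[[i]]] <- pmax(img[foot[[i]]], val)
        }
      } else if (cls == "nuclear") {
        for (i in which(scene$marker_truth[, m]))
          img[foot[[i]]] <- pmax(img[foot[[i]]], foreground)
      } else if (cls == "surface") {
        for (i in which(scene$marker_truth[, m])) {
          idx <- arc_subset(i, band[[i]], m)
          img[idx] <- pmax(img[idx], foreground)
        }
      }
    }
    if (identical(m, panel$epithelial_marker) && nrow(scene$crypts) > 0L) {
      for (k in seq_len(nrow(scene$crypts))) {
        cr <- scene$crypts[k, ]
        outer_idx <- ellipse_indices(cr$row, cr$col, cr$a_out, cr$b_out,
                                     cr$theta, shape)
        inner_idx <- ellipse_indices(cr$row, cr$col, cr$a_out - cr$thickness,
                                     cr$b_out - cr$thickness, cr$theta, shape)
        ann <- setdiff(outer_idx, inner_idx)
        img[ann] <- pmax(img[ann], foreground)
      }
    }
    if (cls == "surface") {
      ed <- scene$spillover_edges
      ed <- ed[ed$marker == m, , drop = FALSE]
      for (k in seq_len(nrow(ed))) {
        s <- ed$source[k]; v <- ed$victim[k]
        dy <- cells$row[s] - cells$row[v]; dx <- cells$col[s] - cells$col[v]
        len <- sqrt(dy^2 + dx^2)
        gv <- sqrt(cells$a[v] * cells$b[v])
        idx <- disk_at(cells$row[v] + dy / len * (gv + 2),
                       cells$col[v] + dx / len * (gv + 2), blob_radius)
        # the artefact sits in the victim's territory: keep it out of the
        # source's own (enlarged) ROI so the source signal stays clean
        idx <- setdiff(idx, ellipse_indices(cells$row[s], cells$col[s],
                                            cells$a[s] + 4, cells$b[s] + 4,
                                            cells$theta[s], shape))
        img[idx] <- pmax(img[idx], ed$strength[k] * aggregate_intensity)
      }
      sp <- scene$speckles
      sp <- sp[sp$marker == m, , drop = FALSE]
      for (k in seq_len(nrow(sp))) {
        idx <- disk_at(sp$row[k], sp$col[k], sp$radius[k])
        img[idx] <- pmax(img[idx], sp$intensity[k])
      }
    }
    out[[m]] <- img
  }
  with_seed(seed, {
    for (m in names(out)) {
      img <- out[[m]] + background
      if (noise_sd > 0)
        img <- img + matrix(rnorm(prod(shape), 0, noise_sd),
                            shape[1], shape[2])
      out[[m]] <- channel_image(pmax(img, 0), m)
    }
  })
  out
}

#' Ground-truth label map of a scene
#'
#' True cell footprints as a [label_map] (label = cell id). Where two
#' footprints marginally overlap the lower id keeps the pixel.
#'
#' @param scene a [synth_scene].
#' @return A [label_map].
#' @export
scene_label_map <- function(scene) {
  labels <- matrix(0L, scene$shape[1], scene$shape[2])
  for (i in seq_len(nrow(scene$cells))) {
    idx <- ellipse_indices(scene$cells$row[i], scene$cells$col[i],
                           scene$cells$a[i], scene$cells$b[i],
                           scene$cells$theta[i], scene$shape)
    idx <- idx[labels[idx] == 0L]
    labels[idx] <- i
  }
  comp <- setNames(scene$cells$compartment, as.character(scene$cells$id))
  label_map(labels, comp)
}

#' Ground-truth enlarged ROI map of a scene
#'
#' The true footprints enlarged by the workflow's ROI-enlargement rule
#' (default 3 px, nearest-seed collision handling) — the reference regions
#' over which ground-truth per-cell intensities are defined.
#'
#' @param scene a [synth_scene].
#' @param by_px enlargement radius.
#' @return A [label_map].
#' @export
scene_roi_map <- function(scene, by_px = 3) {
  enlarge_rois(scene_label_map(scene), by_px)
}

#' Ground-truth per-cell mean intensities
#'
#' Masks the given channels with the true enlarged ROIs and returns one row
#' per cell with the per-marker mean intensity. Used as the oracle for
#' [measure_cells]: feed it a noiseless render passed through the same
#' pre-processing as the pipeline.
#'
#' @param scene a [synth_scene].
#' @param channels named list of [channel_image].
#' @param roi_map ROI [label_map] (default the true enlarged footprints).
#' @return data.frame with `cell_id` and one `mean_<marker>` column per
#'   channel.
#' @export
truth_mean_table <- function(scene, channels, roi_map = scene_roi_map(scene)) {
  pix <- label_index(roi_map$labels)
  ids <- as.integer(names(pix))
  out <- data.frame(cell_id = ids)
  for (m in names(channels)) {
    px <- channels[[m]]$pixels
    out[[paste0("mean_", m)]] <-
      vapply(pix, function(idx) mean(px[idx]), numeric(1))
  }
  out
}

#' Write a scene's ground truth as plain-text tables
#'
#' @param scene a [synth_scene].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_truth <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cbind(scene$cells, as.data.frame(scene$marker_truth))
  write.csv(tab, file.path(dir, "truth_cells.csv"), row.names = FALSE)
  write.csv(scene$spillover_edges, file.path(dir, "truth_spillover.csv"),
            row.names = FALSE)
  write.csv(scene$speckles, file.path(dir, "truth_speckles.csv"),
            row.names = FALSE)
  invisible(dir)
}
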