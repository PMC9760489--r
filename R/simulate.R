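## Synthetic tissue and scRNA-seq generators.
##
## The simulator produces the data structures the downstream pipeline
## consumes — a decoded transcript table, per-cell segmentation polygons at
## the median z-slice, a DAPI raster — together with full ground truth, so
## every stage can be validated against known answers. It emulates the
## salient statistical features of imaging-based spatial data: zonated
## cell-type layout, negative-binomial per-type expression, a sizeable
## extracellular transcript fraction, deliberately bad "empty-space"
## segments with no nucleus under them, optical crowding saturation in
## high-count cells, and a matched sequencing modality with inflated
## dropout.

#' Configuration for the synthetic tissue generator
#'
#' Defaults are the simulator's study conditions: a 900 x 600 um field
#' tiled into 30-um cell slots, ~450 cells, 30% extracellular transcripts,
#' 5% empty-space segments, crowding saturating around 1,000 detected
#' transcripts per cell, seven z-planes 0.7 um apart, and a 1 um/px DAPI
#' raster with bright nuclei over good cells only.
#'
#' @param extent numeric length-2, field size in um (x, y).
#' @param cell_pitch spacing of the cell-slot grid in um.
#' @param n_cells number of real (good) cells to place.
#' @param extracellular_fraction probability a transcript is relocated
#'   outside all polygons (default 0.30).
#' @param bad_segment_fraction bad segments as a fraction of `n_cells`;
#'   these polygons are drawn over empty space (no nucleus, no transcripts).
#' @param crowding list with `enabled` and `saturation_count`; when enabled,
#'   per-cell detected counts are thinned with
#'   probability `1 / (1 + T / saturation_count)` where `T` is the cell's
#'   true total.
#' @param dapi list with `nucleus_mean`, `nucleus_sd`, `background_mean`,
#'   `background_sd` (camera units), `pixel_size` (um/px) and
#'   `nucleus_sigma` (blob width, um).
#' @param n_z number of z-planes (default 7).
#' @param z_spacing spacing between z-planes in um (default 0.7).
#' @param zone_width width of alternating zonation bands along x, in um.
#' @param zone_mixtures optional list of named type-proportion vectors, one
#'   per band (recycled); `NULL` builds an alternating two-zone layout from
#'   the panel's first four cell types.
#' @param seed integer master seed.
#' @return a list of class `tissue_config`.
#' @export
synthetic_tissue_config <- function(extent = c(900, 600), cell_pitch = 30,
                                    n_cells = 450,
                                    extracellular_fraction = 0.30,
                                    bad_segment_fraction = 0.05,
                                    crowding = list(enabled = TRUE,
                                                    saturation_count = 1000),
                                    dapi = list(nucleus_mean = 30000,
                                                nucleus_sd = 3000,
                                                background_mean = 100,
                                                background_sd = 20,
                                                pixel_size = 1,
                                                nucleus_sigma = 4),
                                    n_z = 7, z_spacing = 0.7,
                                    zone_width = 150, zone_mixtures = NULL,
                                    seed = 0L) {
  stopifnot(length(extent) == 2, all(extent > 0), cell_pitch > 0,
            n_cells >= 1,
            extracellular_fraction >= 0, extracellular_fraction <= 1,
            bad_segment_fraction >= 0, bad_segment_fraction <= 1,
            crowding$saturation_count > 0, n_z >= 1, z_spacing > 0,
            dapi$pixel_size > 0, zone_width > 0)
  structure(list(extent = extent, cell_pitch = cell_pitch, n_cells = n_cells,
                 extracellular_fraction = extracellular_fraction,
                 bad_segment_fraction = bad_segment_fraction,
                 crowding = crowding, dapi = dapi, n_z = n_z,
                 z_spacing = z_spacing, zone_width = zone_width,
                 zone_mixtures = zone_mixtures, seed = seed),
            class = "tissue_config")
}

## internal: one random convex polygon inscribed in a slot of size `pitch`
## centred at (cx, cy); radius < pitch/2 keeps slots disjoint
random_cell_polygon <- function(cx, cy, pitch, n_vertices = 10) {
  ## jittered regular angles keep vertices spread out, so no sliver shapes
  ang <- 2 * pi * (seq_len(n_vertices) - 1 +
                     stats::runif(n_vertices, 0.15, 0.85)) / n_vertices
  rad <- stats::runif(n_vertices, 0.38, 0.48) * pitch
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

#' Thin detected molecules to emulate optical crowding
#'
#' In crowded cells the density of fluorescent spots exceeds the diffraction
#' limit and molecules stop being individually resolvable. The simulator
#' models this as molecule-wise thinning: each molecule in a cell with true
#' total count `T` is detected independently with probability
#' `p(T) = 1 / (1 + T / saturation_count)`, so detection degrades smoothly
#' as `T` grows and a cell at `T = saturation_count` keeps half its
#' molecules in expectation.
#'
#' @param true_counts non-negative integer vector (per-gene true counts for
#'   one cell) or a cells x genes matrix.
#' @param saturation_count positive scale of the saturation (counts/cell).
#' @param seed integer seed.
#' @return detected counts, same shape as `true_counts`, elementwise
#'   `<= true_counts`.
#' @export
apply_crowding <- function(true_counts, saturation_count, seed = 0L) {
  stopifnot(saturation_count > 0)
  thin_one <- function(counts) {
    total <- sum(counts)
    p <- 1 / (1 + total / saturation_count)
    stats::rbinom(length(counts), size = counts, prob = p)
  }
  with_seed(split_seed(seed, "crowding"), {
    if (is.matrix(true_counts)) {
      out <- true_counts
      for (i in seq_len(nrow(out))) out[i, ] <- thin_one(true_counts[i, ])
      out
    } else {
      stats::setNames(thin_one(true_counts), names(true_counts))
    }
  })
}

#' Generate a synthetic tissue dataset with ground truth
#'
#' Places cells as disjoint convex polygons on a jittered grid, assigns each
#' cell a type according to a zonated layout (alternating bands along x, so
#' zonated type pairs spatially co-segregate), draws true per-gene counts
#' from the panel's per-type negative-binomial model, optionally thins them
#' for crowding, scatters the detected molecules uniformly inside their
#' cell's polygon across the z-stack, relocates a fraction of them to
#' extracellular space, renders a DAPI raster with nuclei under good cells
#' only, and plants bad segments (polygons over empty background).
#'
#' @param panel a `gene_panel`.
#' @param config a `tissue_config`.
#' @return a list with elements `transcripts` (data.frame gene, x, y, z,
#'   fov, cell_id — unassigned), `segmentation` (see
#'   [segmentation_set()]), `dapi` (see [dapi_image()]) and `truth` (list:
#'   `cells` data.frame with cell_id, type, centroid, is_bad_segment;
#'   `counts_true` and `counts_detected` cells x genes matrices;
#'   `transcript_source` per-transcript cell id, `NA` for extracellular).
#' @export
generate_tissue <- function(panel, config) {
  stopifnot(inherits(panel, "gene_panel"), inherits(config, "tissue_config"))
  pitch <- config$cell_pitch
  nx <- floor(config$extent[1] / pitch)
  ny <- floor(config$extent[2] / pitch)
  n_slots <- nx * ny
  n_bad <- round(config$bad_segment_fraction * config$n_cells)
  if (config$n_cells + n_bad > n_slots) {
    stop_with_class(sprintf(
      "cannot place %d cells + %d bad segments in %d slots",
      config$n_cells, n_bad, n_slots), "tissue_layout_error")
  }

  types <- rownames(panel$type_means)
  mixtures <- config$zone_mixtures
  if (is.null(mixtures)) {
    ## alternating two-zone layout: types 1 & 3 dominate odd bands,
    ## types 2 & 4 even bands, remainder spread uniformly
    base <- stats::setNames(rep(0.30 / max(1, length(types) - 2),
                                length(types)), types)
    mixA <- base; mixA[types[1]] <- 0.55; mixA[types[3]] <- 0.15
    mixB <- base; mixB[types[2]] <- 0.55; mixB[types[4]] <- 0.15
    mixA <- mixA / sum(mixA); mixB <- mixB / sum(mixB)
    mixtures <- list(mixA, mixB)
  }

  master <- config$seed
  slot_xy <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  centers <- cbind(x = (slot_xy$ix + 0.5) * pitch,
                   y = (slot_xy$iy + 0.5) * pitch)

  layout <- with_seed(split_seed(master, "layout"), {
    occ <- sample.int(n_slots, config$n_cells + n_bad)
    good_slots <- occ[seq_len(config$n_cells)]
    bad_slots <- if (n_bad > 0) occ[config$n_cells + seq_len(n_bad)] else integer(0)
    ## zonated type draw per good cell, by the band its slot centre falls in
    band <- (centers[good_slots, "x"] %/% config$zone_width) %% length(mixtures)
    type <- character(config$n_cells)
    for (b in seq_along(mixtures)) {
      sel <- which(band == b - 1)
      if (length(sel)) {
        type[sel] <- sample(names(mixtures[[b]]), length(sel),
                            replace = TRUE, prob = mixtures[[b]])
      }
    }
    list(good_slots = good_slots, bad_slots = bad_slots, type = type)
  })

  n_all <- config$n_cells + n_bad
  cell_ids <- sprintf("cell_%04d", seq_len(n_all))
  all_slots <- c(layout$good_slots, layout$bad_slots)
  polys <- with_seed(split_seed(master, "shapes"), {
    lapply(seq_len(n_all), function(i) {
      random_cell_polygon(centers[all_slots[i], "x"],
                          centers[all_slots[i], "y"], pitch)
    })
  })
  names(polys) <- cell_ids
  is_bad <- c(rep(FALSE, config$n_cells), rep(TRUE, n_bad))

  ## true counts for good cells
  genes <- panel$genes
  counts_true <- with_seed(split_seed(master, "counts"), {
    m <- matrix(0L, n_all, length(genes),
                dimnames = list(cell_ids, genes))
    for (i in seq_len(config$n_cells)) {
      t_i <- layout$type[i]
      m[i, ] <- stats::rnbinom(length(genes),
                               mu = panel$type_means[t_i, ],
                               size = panel$type_dispersions[t_i, ])
    }
    storage.mode(m) <- "integer"
    m
  })

  counts_detected <- counts_true
  if (isTRUE(config$crowding$enabled)) {
    counts_detected <- apply_crowding(counts_true,
                                      config$crowding$saturation_count,
                                      seed = split_seed(master, "thin"))
  }

  ## scatter detected molecules inside their cell polygons
  per_cell <- rowSums(counts_detected)
  total_n <- sum(per_cell)
  tx_gene <- character(total_n); tx_x <- tx_y <- numeric(total_n)
  tx_src <- character(total_n)
  pos <- 0L
  with_seed(split_seed(master, "place"), {
    for (i in seq_len(n_all)) {
      n_i <- per_cell[i]
      if (n_i == 0) next
      poly <- polys[[i]]
      bb <- c(range(poly[, 1]), range(poly[, 2]))
      pts <- matrix(NA_real_, 0, 2)
      while (nrow(pts) < n_i) {
        k <- max(2 * (n_i - nrow(pts)), 20)
        cand <- cbind(stats::runif(k, bb[1], bb[2]),
                      stats::runif(k, bb[3], bb[4]))
        cand <- cand[points_in_polygon(cand, poly), , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts <- pts[seq_len(n_i), , drop = FALSE]
      idx <- pos + seq_len(n_i)
      tx_gene[idx] <- rep(genes, counts_detected[i, ])
      tx_x[idx] <- pts[, 1]; tx_y[idx] <- pts[, 2]
      tx_src[idx] <- cell_ids[i]
      pos <- pos + n_i
    }
  })
  tx_z <- with_seed(split_seed(master, "zplane"),
                    sample.int(config$n_z, total_n, replace = TRUE) - 1L)

  ## relocate a fraction to extracellular space; polygons are inscribed in
  ## their grid slot, so "outside all polygons" only needs the slot's polygon
  is_extra <- with_seed(split_seed(master, "extra"),
                        stats::runif(total_n) < config$extracellular_fraction)
  slot_of <- integer(n_slots); slot_of[all_slots] <- seq_len(n_all)
  n_extra <- sum(is_extra)
  if (n_extra > 0) {
    out_pts <- with_seed(split_seed(master, "extra_place"), {
      got <- matrix(NA_real_, 0, 2)
      while (nrow(got) < n_extra) {
        k <- max(2 * (n_extra - nrow(got)), 20)
        cand <- cbind(stats::runif(k, 0, nx * pitch),
                      stats::runif(k, 0, ny * pitch))
        ix <- pmin(nx - 1, cand[, 1] %/% pitch)
        iy <- pmin(ny - 1, cand[, 2] %/% pitch)
        cell_of <- slot_of[ix + iy * nx + 1]
        inside <- logical(k)
        for (ci in unique(cell_of[cell_of > 0])) {
          sel <- which(cell_of == ci)
          inside[sel] <- points_in_polygon(cand[sel, , drop = FALSE],
                                           polys[[ci]])
        }
        got <- rbind(got, cand[!inside, , drop = FALSE])
      }
      got[seq_len(n_extra), , drop = FALSE]
    })
    tx_x[is_extra] <- out_pts[, 1]
    tx_y[is_extra] <- out_pts[, 2]
  }
  tx_src[is_extra] <- NA_character_

  transcripts <- data.frame(gene = tx_gene, x = tx_x, y = tx_y, z = tx_z,
                            fov = 1L, cell_id = NA_character_,
                            stringsAsFactors = FALSE)

  dapi <- render_dapi(polys, centers[layout$good_slots, , drop = FALSE],
                      config, seed = split_seed(master, "dapi"))

  segmentation <- segmentation_set(polys, n_z = config$n_z,
                                   median_z_index = (config$n_z - 1L) %/% 2L)

  centroids <- t(vapply(polys, colMeans, numeric(2)))
  truth <- list(
    cells = data.frame(cell_id = cell_ids,
                       type = c(layout$type, rep(NA_character_, n_bad)),
                       x = centroids[, 1], y = centroids[, 2],
                       is_bad_segment = is_bad, stringsAsFactors = FALSE),
    counts_true = counts_true,
    counts_detected = counts_detected,
    transcript_source = tx_src)

  list(transcripts = transcripts, segmentation = segmentation, dapi = dapi,
       truth = truth, panel = panel, config = config)
}

## internal: render the DAPI raster — Gaussian nucleus blobs at good-cell
## centroids over Gaussian background, 16-bit clipped
render_dapi <- function(polys, good_centers, config, seed) {
  px <- config$dapi$pixel_size
  n_col <- ceiling(config$extent[1] / px)
  n_row <- ceiling(config$extent[2] / px)
  with_seed(seed, {
    img <- matrix(stats::rnorm(n_row * n_col, config$dapi$background_mean,
                               config$dapi$background_sd), n_row, n_col)
    sig <- config$dapi$nucleus_sigma / px
    half <- ceiling(4 * sig)
    for (i in seq_len(nrow(good_centers))) {
      amp <- stats::rnorm(1, config$dapi$nucleus_mean, config$dapi$nucleus_sd)
      cc <- good_centers[i, 1] / px + 0.5  # pixel-centre coordinates
      cr <- good_centers[i, 2] / px + 0.5
      cols <- max(1, floor(cc - half)):min(n_col, ceiling(cc + half))
      rows <- max(1, floor(cr - half)):min(n_row, ceiling(cr + half))
      blob <- outer(rows - cr, cols - cc,
                    function(dr, dc) exp(-(dr^2 + dc^2) / (2 * sig^2)))
      img[rows, cols] <- img[rows, cols] + amp * blob
    }
    img <- round(pmin(pmax(img, 0), 65535))
    dapi_image(img, pixel_size = px)
  })
}

#' Generate a matched synthetic scRNA-seq count matrix
#'
#' Draws counts from the same per-type negative-binomial model as the tissue
#' generator, then zeroes each cell-gene entry independently with
#' probability `dropout_inflation`, emulating the higher dropout of a
#' dissociative sequencing modality relative to imaging.
#'
#' @param panel a `gene_panel`.
#' @param n_cells number of cells.
#' @param type_proportions named numeric vector over the panel's cell
#'   types, summing to 1; `NULL` for uniform.
#' @param dropout_inflation per-entry zeroing probability (default 0.5,
#'   the conservative end of the capture-efficiency gap between droplet
#'   sequencing and imaging).
#' @param seed integer seed.
#' @return list with `counts` (cells x genes integer matrix) and `labels`
#'   (character vector of true types per cell).
#' @export
generate_scrna <- function(panel, n_cells, type_proportions = NULL,
                           dropout_inflation = 0.5, seed = 0L) {
  stopifnot(inherits(panel, "gene_panel"), n_cells >= 1,
            dropout_inflation >= 0, dropout_inflation <= 1)
  types <- rownames(panel$type_means)
  if (is.null(type_proportions)) {
    type_proportions <- stats::setNames(rep(1 / length(types), length(types)),
                                        types)
  }
  stopifnot(abs(sum(type_proportions) - 1) < 1e-8,
            all(names(type_proportions) %in% types))
  genes <- panel$genes
  with_seed(split_seed(seed, "scrna"), {
    labels <- sample(names(type_proportions), n_cells, replace = TRUE,
                     prob = type_proportions)
    counts <- matrix(0L, n_cells, length(genes),
                     dimnames = list(sprintf("sc_%05d", seq_len(n_cells)),
                                     genes))
    for (t in unique(labels)) {
      sel <- which(labels == t)
      draws <- stats::rnbinom(length(sel) * length(genes),
                              mu = rep(panel$type_means[t, ], each = length(sel)),
                              size = rep(panel$type_dispersions[t, ],
                                         each = length(sel)))
      counts[sel, ] <- matrix(draws, length(sel), length(genes))
    }
    storage.mode(counts) <- "integer"
    if (dropout_inflation > 0) {
      drop <- matrix(stats::runif(length(counts)) < dropout_inflation,
                     nrow(counts), ncol(counts))
      counts[drop] <- 0L
    }
    list(counts = counts, labels = stats::setNames(labels, rownames(counts)))
  })
}
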