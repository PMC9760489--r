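## Transcript-to-cell assignment ("cookie cutter").
##
## Segmentation is 2D at the median z-slice; its xy boundary is projected
## through the whole z-stack, so a transcript at any z-plane belongs to the
## cell whose median-z polygon contains its (x, y). Geometry primitives
## (point-in-polygon, shoelace area, pixel-centre DAPI averaging) live here.
##
## Conventions, used everywhere: coordinates in um, origin at the mosaic
## top-left, x rightward, y downward, z-plane indices 0-based; raster pixel
## (row i, col j), 1-based in R, has its centre at
## ((j - 0.5), (i - 0.5)) * pixel_size. Points on a polygon boundary count
## as inside.

#' Construct a segmentation set
#'
#' @param polygons named list of cell polygons, each an n x 2 numeric matrix
#'   of vertices in um (median z-slice boundary). Rings may be given open or
#'   closed; a closing vertex equal to the first is dropped.
#' @param n_z total number of z-planes in the stack.
#' @param median_z_index 0-based index of the median plane (e.g. 3 for the
#'   4th of 7).
#' @return an object of class `segmentation_set`.
#' @export
segmentation_set <- function(polygons, n_z = 7,
                             median_z_index = (n_z - 1) %/% 2) {
  stopifnot(is.list(polygons), length(polygons) >= 1,
            !is.null(names(polygons)), !anyDuplicated(names(polygons)))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3, all(is.finite(p)))
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  structure(list(polygons = polygons, n_z = as.integer(n_z),
                 median_z_index = as.integer(median_z_index)),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("segmentation_set: %d cells, %d z-planes (median index %d)\n",
              length(x$polygons), x$n_z, x$median_z_index))
  invisible(x)
}

#' Construct a DAPI intensity image
#'
#' @param raster numeric matrix of non-negative intensities (camera units);
#'   rows are y (downward), columns are x.
#' @param pixel_size pixel edge length in um/px.
#' @param origin length-2 offset of the raster's top-left corner in um.
#' @return an object of class `dapi_image`.
#' @export
dapi_image <- function(raster, pixel_size, origin = c(0, 0)) {
  raster <- as.matrix(raster)
  stopifnot(all(raster >= 0), pixel_size > 0, length(origin) == 2)
  structure(list(raster = raster, pixel_size = pixel_size, origin = origin),
            class = "dapi_image")
}

#' Point-in-polygon membership, boundary inclusive
#'
#' Even-odd (ray casting) membership test with an explicit on-boundary
#' check: points lying on a polygon edge or vertex count as inside.
#'
#' @param points n x 2 numeric matrix of (x, y), or a length-2 vector.
#' @param polygon m x 2 numeric matrix of vertices (open ring, m >= 3).
#' @param eps tolerance for the on-boundary test (default 1e-9 um).
#' @return logical vector of length n.
#' @export
points_in_polygon <- function(points, polygon, eps = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) {
    stop_with_class("degenerate polygon: fewer than 3 vertices",
                    "degenerate_polygon")
  }
  if (polygon_area(polygon, .check = FALSE) <= eps^2) {
    stop_with_class("degenerate polygon: zero area", "degenerate_polygon")
  }
  px <- points[, 1]; py <- points[, 2]
  n <- length(px)
  inside <- logical(n)
  on_edge <- logical(n)
  vx <- polygon[, 1]; vy <- polygon[, 2]
  m <- length(vx)
  j <- m
  for (i in seq_len(m)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    ## on-segment: collinear and within the bounding box of the edge
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on_seg <- abs(cross) <= eps * max(seg_len, 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    ## ray-casting: horizontal ray to +x, half-open rule in y
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Shoelace polygon area
#'
#' @param polygon m x 2 vertex matrix (open ring).
#' @param .check internal; skip degeneracy error.
#' @return area in um^2, positive regardless of vertex orientation.
#' @export
polygon_area <- function(polygon, .check = TRUE) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) {
    stop_with_class("degenerate polygon: fewer than 3 vertices",
                    "degenerate_polygon")
  }
  x <- polygon[, 1]; y <- polygon[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  a <- abs(sum(x * ys - xs * y)) / 2
  if (.check && a == 0) {
    stop_with_class("degenerate polygon: zero area", "degenerate_polygon")
  }
  a
}

#' Assign transcripts to cells by the projected median-z boundary
#'
#' Each transcript, at any z-plane, is assigned to the cell whose median
#' z-slice polygon contains its (x, y); transcripts in no polygon get
#' `NA` in `cell_id`. Where polygons overlap, the smallest-area containing
#' polygon wins; ties break to the lexicographically smallest cell id.
#'
#' @param transcripts data.frame with columns `gene`, `x`, `y`, `z` (and
#'   optionally `fov`, `cell_id`; an existing `cell_id` is overwritten).
#' @param segmentation a `segmentation_set`.
#' @return the transcript table with `cell_id` filled (`NA` = unassigned);
#'   every input row appears exactly once, in input order.
#' @export
assign_transcripts <- function(transcripts, segmentation) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene", "x", "y", "z") %in% names(transcripts)),
            inherits(segmentation, "segmentation_set"))
  polys <- segmentation$polygons
  areas <- vapply(polys, polygon_area, numeric(1))
  ## smallest-area-first with lexicographic tie-break: the first polygon in
  ## this order that contains a point is its assignment
  ord <- order(areas, names(polys))
  assigned <- rep(NA_character_, nrow(transcripts))
  px <- transcripts$x; py <- transcripts$y
  for (k in ord) {
    todo <- which(is.na(assigned))
    if (!length(todo)) break
    poly <- polys[[k]]
    bb_x <- range(poly[, 1]); bb_y <- range(poly[, 2])
    cand <- todo[px[todo] >= bb_x[1] & px[todo] <= bb_x[2] &
                   py[todo] >= bb_y[1] & py[todo] <= bb_y[2]]
    if (!length(cand)) next
    hit <- points_in_polygon(cbind(px[cand], py[cand]), poly)
    assigned[cand[hit]] <- names(polys)[k]
  }
  transcripts$cell_id <- assigned
  transcripts
}

#' Fraction of transcripts assigned to a cell
#'
#' @param transcripts transcript table with `cell_id` (`NA` = unassigned).
#' @return `(# assigned) / (# total)`.
#' @export
assignable_fraction <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) > 0,
            "cell_id" %in% names(transcripts))
  mean(!is.na(transcripts$cell_id))
}

#' Average DAPI intensity inside a polygon
#'
#' Mean raster intensity over the pixels whose centres fall inside the
#' polygon (pixel-centre membership, not area weighting). This is the
#' per-cell segmentation-alignment score: a boundary drawn over empty space
#' has no nucleus under it and scores near background.
#'
#' @param polygon m x 2 vertex matrix in um.
#' @param dapi a `dapi_image`.
#' @return mean intensity in camera units.
#' @export
compute_average_dapi <- function(polygon, dapi) {
  stopifnot(inherits(dapi, "dapi_image"))
  px <- dapi$pixel_size
  r <- dapi$raster
  ## candidate pixel window from the polygon bounding box
  bx <- range(polygon[, 1]) - dapi$origin[1]
  by <- range(polygon[, 2]) - dapi$origin[2]
  cols <- max(1, floor(bx[1] / px + 0.5)):min(ncol(r), ceiling(bx[2] / px + 0.5))
  rows <- max(1, floor(by[1] / px + 0.5)):min(nrow(r), ceiling(by[2] / px + 0.5))
  if (!length(cols) || !length(rows)) {
    stop_with_class("polygon contains no pixel centres", "empty_pixel_set")
  }
  grid <- expand.grid(row = rows, col = cols)
  centres <- cbind(dapi$origin[1] + (grid$col - 0.5) * px,
                   dapi$origin[2] + (grid$row - 0.5) * px)
  inside <- points_in_polygon(centres, polygon)
  if (!any(inside)) {
    stop_with_class("polygon contains no pixel centres", "empty_pixel_set")
  }
  mean(r[cbind(grid$row[inside], grid$col[inside])])
}

#' Build the per-cell table and count matrix from assigned transcripts
#'
#' One row per segmented cell (cells with zero assigned transcripts
#' included), with centroid, shoelace area, total counts, average DAPI
#' score, and a cells x genes count matrix whose grand total equals the
#' number of assigned transcripts exactly.
#'
#' @param assigned transcript table with `cell_id` filled by
#'   [assign_transcripts()].
#' @param segmentation a `segmentation_set`.
#' @param dapi a `dapi_image`, or `NULL` to skip the DAPI score
#'   (`avg_dapi` becomes `NA`).
#' @param genes optional character vector fixing the count-matrix columns
#'   (e.g. the full panel); defaults to the genes observed.
#' @return list with `cells` (data.frame: cell_id, x, y, area_um2,
#'   total_counts, avg_dapi) and `counts` (cells x genes integer matrix).
#' @export
build_cell_table <- function(assigned, segmentation, dapi = NULL,
                             genes = NULL) {
  stopifnot(inherits(segmentation, "segmentation_set"),
            "cell_id" %in% names(assigned))
  ids <- names(segmentation$polygons)
  known <- is.na(assigned$cell_id) | assigned$cell_id %in% ids
  if (!all(known)) {
    stop_with_class(sprintf("transcripts reference unknown cell ids: %s",
                            paste(utils::head(unique(
                              assigned$cell_id[!known])), collapse = ", ")),
                    "unknown_cell_id")
  }
  if (is.null(genes)) genes <- sort(unique(assigned$gene))
  asg <- assigned[!is.na(assigned$cell_id), c("gene", "cell_id")]
  counts_tab <- table(factor(asg$cell_id, levels = ids),
                      factor(asg$gene, levels = genes))
  counts <- matrix(as.integer(counts_tab), nrow = length(ids),
                   dimnames = list(ids, genes))

  centroids <- t(vapply(segmentation$polygons, colMeans, numeric(2)))
  areas <- vapply(segmentation$polygons, polygon_area, numeric(1))
  avg_dapi <- if (is.null(dapi)) rep(NA_real_, length(ids)) else {
    vapply(segmentation$polygons, compute_average_dapi, numeric(1),
           dapi = dapi)
  }
  cells <- data.frame(cell_id = ids,
                      x = centroids[, 1], y = centroids[, 2],
                      area_um2 = areas,
                      total_counts = as.integer(rowSums(counts)),
                      avg_dapi = avg_dapi,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(cells = cells, counts = counts)
}
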