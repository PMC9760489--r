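# Shared fixtures, built in code at test time.

# compact panel: 40 genes, 4 cell types, 5 markers each — fast but keeps
# the marker/baseline/off-tissue structure of the full panel
small_panel <- function(seed = 11) {
  synthetic_panel(n_genes = 40, n_types = 4, n_marker = 5, seed = seed)
}

# tiny tissue: ~60 cells on a 300 x 240 um field
small_tissue_config <- function(seed = 7, ...) {
  args <- list(extent = c(300, 240), n_cells = 60,
               bad_segment_fraction = 0, extracellular_fraction = 0,
               crowding = list(enabled = FALSE, saturation_count = 1000),
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_tissue_config, args)
}

# brute-force per-anchor co-occurrence oracle: explicit loops over anchors,
# no shared code with cooccurrence_ratio()
oracle_cooccurrence <- function(cells, bin_edges) {
  labs <- sort(unique(cells$label))
  L <- length(labs)
  edges <- c(0, bin_edges)
  n_bins <- length(bin_edges)
  C <- array(0, dim = c(L, L, n_bins))  # [anchor label, neighbour label, band]
  for (a in seq_len(nrow(cells))) {
    dx <- cells$x - cells$x[a]; dy <- cells$y - cells$y[a]
    d <- sqrt(dx^2 + dy^2)
    for (b in seq_len(n_bins)) {
      nb <- which(d > edges[b] & d <= edges[b + 1])
      nb <- setdiff(nb, a)
      if (!length(nb)) next
      ja <- match(cells$label[a], labs)
      for (i in seq_len(L)) {
        C[ja, i, b] <- C[ja, i, b] + sum(cells$label[nb] == labs[i])
      }
    }
  }
  R <- array(NA_real_, dim = c(L, L, n_bins))
  for (b in seq_len(n_bins)) {
    tot <- sum(C[, , b])
    if (tot == 0) next
    p_i <- colSums(C[, , b, drop = FALSE][, , 1]) / tot
    for (j in seq_len(L)) {
      rj <- sum(C[j, , b])
      if (rj == 0) next
      p_ij <- C[j, , b] / rj
      R[, j, b] <- ifelse(p_i > 0, p_ij / p_i, NA_real_)
    }
  }
  list(labels = labs, R = R)
}

# rasterization point-in-polygon oracle: point is inside iff its containing
# fine-raster pixel centre is inside by winding of the rasterized mask —
# here directly: classify by sign of winding number computed from angles
oracle_point_in_polygon <- function(px, py, poly) {
  # total signed angle subtended by the polygon around the point
  vx <- c(poly[, 1], poly[1, 1]) - px
  vy <- c(poly[, 2], poly[1, 2]) - py
  ang <- diff(atan2(vy, vx))
  ang <- ifelse(ang > pi, ang - 2 * pi, ifelse(ang < -pi, ang + 2 * pi, ang))
  abs(sum(ang)) > pi  # ~2*pi inside, ~0 outside
}
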