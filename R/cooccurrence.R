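## Spatial cell-type co-occurrence.
##
## For an ordered label pair (i, j) and a distance band (d_lo, d_hi], the
## co-occurrence ratio is
##
##     R(d) = P(i | j, d) / P(i, d)
##
## where P(i | j, d) is the fraction of label-i cells among all neighbours
## within the band of label-j anchor cells (pooled over anchors, the anchor
## itself excluded) and P(i, d) the same fraction pooled over all anchors.
## Under spatial independence of the labels R = 1; R > 1 means type i is
## enriched near type j. The estimator is the pooled band-count form (not a
## per-anchor average of ratios): it is the plain conditional-probability
## estimator and is directly checkable against exhaustive pair counting.

#' Cell-type co-occurrence probability ratio over distance bands
#'
#' @param cells data.frame with columns `x`, `y` (um) and `label`.
#' @param bin_edges strictly increasing numeric vector of band edges in um,
#'   first edge > 0; bands are half-open `(lo, hi]`. Default: 25 linear
#'   bands from 0 to 1,000 um.
#' @return object of class `cooccurrence_result`: list with `labels`,
#'   `bin_edges`, `R` (3-d array label_i x label_j x band; `NA` where the
#'   band holds no neighbours of label-j anchors), and `support` (matrix
#'   label_j x band: pooled neighbour counts).
#' @export
cooccurrence_ratio <- function(cells,
                               bin_edges = seq(0, 1000, length.out = 26)[-1]) {
  stopifnot(is.data.frame(cells),
            all(c("x", "y", "label") %in% names(cells)))
  if (nrow(cells) < 2) {
    stop_with_class("need at least 2 cells", "cooccurrence_degenerate")
  }
  stopifnot(all(is.finite(cells$x)), all(is.finite(cells$y)))
  bin_edges <- as.numeric(bin_edges)
  if (!length(bin_edges) || any(diff(c(0, bin_edges)) <= 0) ||
      bin_edges[1] <= 0) {
    stop_with_class("bin_edges must be strictly increasing and start > 0",
                    "cooccurrence_degenerate")
  }

  labs <- sort(unique(cells$label))
  lab_idx <- match(cells$label, labs)
  n <- nrow(cells)
  n_bins <- length(bin_edges)
  edges <- c(0, bin_edges)

  ## pairwise distances; self-pairs excluded below
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  pair_i <- rep(seq_len(n), times = n)   # anchor index (column-major rows)
  pair_j <- rep(seq_len(n), each = n)    # neighbour index
  keep <- pair_i != pair_j
  dv <- as.vector(d)[keep]
  anchor_lab <- lab_idx[pair_i[keep]]
  neigh_lab <- lab_idx[pair_j[keep]]
  ## (lo, hi] bands; coincident points (d = 0) fall in no band
  band <- findInterval(dv, edges, left.open = TRUE)
  in_range <- band >= 1 & band <= n_bins

  L <- length(labs)
  R <- array(NA_real_, dim = c(L, L, n_bins),
             dimnames = list(label_i = labs, label_j = labs,
                             band = paste0("(", edges[-length(edges)], ",",
                                           bin_edges, "]")))
  support <- matrix(0, L, n_bins, dimnames = list(label_j = labs, NULL))

  for (b in seq_len(n_bins)) {
    sel <- in_range & band == b
    if (!any(sel)) next
    ## C[j, i] = # ordered pairs (anchor of label j, neighbour of label i)
    C <- table(factor(anchor_lab[sel], levels = seq_len(L)),
               factor(neigh_lab[sel], levels = seq_len(L)))
    C <- matrix(as.numeric(C), L, L)
    row_tot <- rowSums(C)           # neighbours pooled per anchor label
    tot <- sum(C)
    p_i <- colSums(C) / tot         # P(i, d)
    support[, b] <- row_tot
    for (j in seq_len(L)) {
      if (row_tot[j] == 0) next
      p_ij <- C[j, ] / row_tot[j]   # P(i | j, d)
      R[, j, b] <- ifelse(p_i > 0, p_ij / p_i, NA_real_)
    }
  }

  structure(list(labels = labs, bin_edges = bin_edges, R = R,
                 support = support),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf(
    "cooccurrence_result: %d labels, %d distance bands up to %g um\n",
    length(x$labels), length(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Flatten a co-occurrence result to long format
#'
#' @param result a `cooccurrence_result`.
#' @return data.frame with label_i, label_j, bin_lo, bin_hi, R, n_support.
#' @export
cooccurrence_long <- function(result) {
  stopifnot(inherits(result, "cooccurrence_result"))
  labs <- result$labels
  edges <- c(0, result$bin_edges)
  rows <- expand.grid(label_i = labs, label_j = labs,
                      band = seq_along(result$bin_edges),
                      stringsAsFactors = FALSE)
  rows$bin_lo <- edges[rows$band]
  rows$bin_hi <- result$bin_edges[rows$band]
  rows$R <- result$R[cbind(match(rows$label_i, labs),
                           match(rows$label_j, labs), rows$band)]
  rows$n_support <- result$support[cbind(match(rows$label_j, labs),
                                         rows$band)]
  rows$band <- NULL
  rows
}
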