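## Gene panels: the set of targeted marker genes together with the per
## cell-type negative-binomial expression model used by the simulators.

#' Construct a gene panel
#'
#' A panel binds gene names to an organ class (the organ whose cell types the
#' gene marks) and to a per-cell-type negative-binomial expression model:
#' `type_means[t, g]` is the NB mean of gene `g` in cell type `t`, and
#' `type_dispersions[t, g]` the NB size parameter `r`
#' (variance = mu + mu^2 / r).
#'
#' @param genes character vector of unique gene names.
#' @param organ_class character vector, one of `"liver"`, `"kidney"`,
#'   `"pancreas"` per gene.
#' @param type_means numeric matrix, cell types x genes, non-negative.
#' @param type_dispersions numeric matrix, cell types x genes, positive.
#' @return an object of class `gene_panel`.
#' @export
gene_panel <- function(genes, organ_class, type_means, type_dispersions) {
  stopifnot(!anyDuplicated(genes),
            length(organ_class) == length(genes),
            all(organ_class %in% c("liver", "kidney", "pancreas")),
            is.matrix(type_means), ncol(type_means) == length(genes),
            all(type_means >= 0),
            identical(dim(type_means), dim(type_dispersions)),
            all(type_dispersions > 0),
            !is.null(rownames(type_means)))
  colnames(type_means) <- colnames(type_dispersions) <- genes
  rownames(type_dispersions) <- rownames(type_means)
  structure(list(genes = genes, organ_class = organ_class,
                 type_means = type_means,
                 type_dispersions = type_dispersions),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes (%s), %d cell types\n",
              length(x$genes),
              paste(sprintf("%s %d", names(table(x$organ_class)),
                            table(x$organ_class)), collapse = ", "),
              nrow(x$type_means)))
  invisible(x)
}

#' Build a synthetic three-organ marker panel
#'
#' Emulates a marker-gene panel of the kind used for multi-organ imaging
#' panels: `n_genes` genes split across liver, kidney and pancreas marker
#' pools, with `n_marker` marker genes per cell type drawn from the tissue's
#' own pool. Marker genes get elevated NB means in their cell type; all
#' other genes sit at a low baseline. Pancreas genes mark no tissue cell
#' type, so in a liver- or kidney-like simulation they behave as an
#' off-tissue false-positive control.
#'
#' Cell-type names follow liver conventions (periportal/pericentral
#' hepatocytes and endothelial cells, Kupffer cells, stellate cells, immune
#' cells, bile-duct epithelium, plus two generic epithelial types) purely as
#' labels; the expression model is what downstream code consumes.
#'
#' @param n_genes total panel size (default 307).
#' @param n_types number of cell types (default 10).
#' @param n_marker marker genes per cell type (default 10).
#' @param marker_mean mean NB expression of a marker gene in its own type
#'   (default 20 counts/cell).
#' @param baseline_mean NB mean of a non-marker gene (default 0.3).
#' @param dispersion NB size parameter used for all genes (default 3).
#' @param seed integer seed for the marker-mean jitter.
#' @return a `gene_panel`.
#' @export
synthetic_panel <- function(n_genes = 307, n_types = 10, n_marker = 10,
                            marker_mean = 20, baseline_mean = 0.3,
                            dispersion = 3, seed = 0L) {
  stopifnot(n_types >= 2, n_marker * n_types <= n_genes)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  ## roughly 40/40/20 liver/kidney/pancreas split
  n_liv <- round(0.4 * n_genes); n_kid <- round(0.4 * n_genes)
  organ <- rep(c("liver", "kidney", "pancreas"),
               c(n_liv, n_kid, n_genes - n_liv - n_kid))

  types <- c("PP-hep", "PC-hep", "PP-EC", "PC-EC", "KC",
             "HSC", "IC", "BD-EC", "epi-A", "epi-B")[seq_len(n_types)]
  if (n_types > 10) {
    types <- c(types, sprintf("type_%02d", seq_len(n_types - 10) + 10))
  }

  mu <- matrix(baseline_mean, n_types, n_genes,
               dimnames = list(types, genes))
  ## markers come from the liver+kidney pools only; pancreas genes stay at
  ## baseline everywhere and then get knocked down to near zero below
  tissue_pool <- which(organ != "pancreas")
  stopifnot(n_marker * n_types <= length(tissue_pool))
  with_seed(split_seed(seed, "panel"), {
    for (t in seq_len(n_types)) {
      idx <- tissue_pool[((t - 1) * n_marker + 1):(t * n_marker)]
      mu[t, idx] <- marker_mean * exp(stats::rnorm(n_marker, 0, 0.35))
    }
  })
  ## off-tissue control genes: essentially absent from the simulated tissue
  mu[, organ == "pancreas"] <- baseline_mean / 25

  disp <- matrix(dispersion, n_types, n_genes,
                 dimnames = list(types, genes))
  gene_panel(genes, organ, mu, disp)
}
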