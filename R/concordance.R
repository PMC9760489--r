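## Concordance statistics between modalities.
##
## Bulk-level: per-gene totals, pseudo-bulk, and Pearson correlation on
## log-transformed totals. Single-cell level: total counts, per-cell dropout
## rates, per-gene detection fractions, nonzero-cell means with SEM,
## mean-variance analysis, maximum-likelihood negative-binomial fits,
## crowding diagnostics, and the standard clustering normalization.

#' Per-gene total counts (bulk profile)
#'
#' Sums counts per gene across an entire dataset — from a cells x genes
#' count matrix or from a transcript table — including zeros for panel
#' genes never detected.
#'
#' @param x count matrix (cells x genes) or transcript table with a `gene`
#'   column.
#' @param genes optional character vector fixing the gene universe;
#'   defaults to the matrix columns / observed genes.
#' @return named numeric vector of per-gene totals.
#' @export
bulk_gene_totals <- function(x, genes = NULL) {
  if (is.data.frame(x) && "gene" %in% names(x)) {
    if (is.null(genes)) genes <- sort(unique(x$gene))
    tab <- table(factor(x$gene, levels = genes))
    stats::setNames(as.numeric(tab), genes)
  } else {
    x <- as.matrix(x)
    tot <- colSums(x)
    if (!is.null(genes)) {
      out <- stats::setNames(numeric(length(genes)), genes)
      shared <- intersect(genes, names(tot))
      out[shared] <- tot[shared]
      out
    } else tot
  }
}

#' Pseudo-bulk profile from a spot or cell matrix
#'
#' Sums all detected RNA over spots/cells — the standard way to compare a
#' non-single-cell spatial assay at the bulk level. Identical to
#' [bulk_gene_totals()] on a matrix; kept as its own verb for clarity.
#'
#' @param spot_matrix spots/cells x genes count matrix.
#' @return named numeric vector of per-gene totals.
#' @export
pseudobulk <- function(spot_matrix) {
  bulk_gene_totals(spot_matrix)
}

#' Pearson correlation of log-transformed bulk profiles
#'
#' Correlates `log10(1 + count)` across the genes shared by the two
#' profiles. Symmetric in its arguments and invariant to gene reordering.
#'
#' @param a,b named numeric vectors of per-gene totals.
#' @return list with `r` (Pearson correlation) and `n_genes` used.
#' @export
log_correlation <- function(a, b) {
  stopifnot(!is.null(names(a)), !is.null(names(b)))
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) {
    stop_with_class("fewer than 3 shared genes", "log_correlation_error")
  }
  la <- log10(1 + a[shared]); lb <- log10(1 + b[shared])
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    stop_with_class("zero variance in a log-profile", "log_correlation_error")
  }
  list(r = stats::cor(la, lb), n_genes = length(shared))
}

#' Total transcript counts per cell
#'
#' @param counts cells x genes count matrix.
#' @return named numeric vector of row sums.
#' @export
total_counts_per_cell <- function(counts) {
  rowSums(as.matrix(counts))
}

#' Per-cell dropout rates against a fixed panel
#'
#' Dropout for a cell is the fraction of the whole gene panel with zero
#' counts in that cell: `(panel_size - # genes detected) / panel_size`.
#'
#' @param counts cells x genes count matrix (columns a subset of the
#'   panel).
#' @param panel_size total number of genes in the panel (default: number
#'   of columns).
#' @return named numeric vector in [0, 1] per cell.
#' @export
dropout_rates <- function(counts, panel_size = ncol(counts)) {
  counts <- as.matrix(counts)
  detected <- rowSums(counts > 0)
  if (panel_size < max(detected)) {
    stop_with_class("panel_size smaller than detected gene count",
                    "dropout_panel_error")
  }
  (panel_size - detected) / panel_size
}

#' Per-gene detection fractions
#'
#' Fraction of cells with nonzero counts for each gene — the per-gene
#' sensitivity view complementary to the per-cell dropout rate.
#'
#' @param counts cells x genes count matrix with at least one cell.
#' @return named numeric vector in [0, 1] per gene.
#' @export
detection_fractions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) {
    stop_with_class("empty count matrix", "detection_empty")
  }
  colMeans(counts > 0)
}

#' Per-gene mean and SEM over cells with nonzero counts
#'
#' Computes, for each gene with at least `min_cells` nonzero cells, the
#' plain mean and standard error of the mean (sample SD with n-1
#' denominator over sqrt(n)) across the nonzero cells only. Genes below the
#' support threshold are excluded (reported with `qualified = FALSE`).
#'
#' @param counts cells x genes count matrix.
#' @param min_cells minimum number of nonzero cells per gene (default 50).
#' @return data.frame with gene, mean, sem, n_nonzero, qualified.
#' @export
nonzero_gene_means <- function(counts, min_cells = 50) {
  stopifnot(min_cells >= 2)
  counts <- as.matrix(counts)
  out <- lapply(colnames(counts), function(g) {
    v <- counts[, g]; v <- v[v > 0]
    n <- length(v)
    if (n >= min_cells) {
      data.frame(gene = g, mean = mean(v),
                 sem = stats::sd(v) / sqrt(n),
                 n_nonzero = n, qualified = TRUE)
    } else {
      data.frame(gene = g, mean = NA_real_, sem = NA_real_,
                 n_nonzero = n, qualified = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Mean-variance points over cells with nonzero counts
#'
#' Per qualifying gene, the sample mean and sample variance (n-1
#' denominator) of counts across nonzero cells. Overdispersion shows as
#' points above the variance = mean (Poisson) line.
#'
#' @param counts cells x genes count matrix.
#' @param min_cells minimum nonzero cells per gene (default 50).
#' @return data.frame with gene, mean, variance, n_nonzero for qualifying
#'   genes.
#' @export
mean_variance <- function(counts, min_cells = 50) {
  stopifnot(min_cells >= 2)
  counts <- as.matrix(counts)
  out <- lapply(colnames(counts), function(g) {
    v <- counts[, g]; v <- v[v > 0]
    if (length(v) >= min_cells) {
      data.frame(gene = g, mean = mean(v), variance = stats::var(v),
                 n_nonzero = length(v))
    }
  })
  do.call(rbind, out)
}

#' Maximum-likelihood negative-binomial fit
#'
#' Fits the NB(mu, r) model with variance `mu + mu^2 / r` by maximum
#' likelihood. The MLE of `mu` is the sample mean; `r` is found by
#' maximizing the profile log-likelihood over `log(r)` (Brent), initialized
#' at the method-of-moments estimate `r0 = mean^2 / (var - mean)`.
#' Samples whose variance does not exceed the mean are at the Poisson
#' boundary of the NB family; these return `poisson_limit = TRUE` with `r`
#' set to the documented sentinel `1e8`.
#'
#' @param counts vector of non-negative integer counts, length >= 30, with
#'   nonzero variance.
#' @return object of class `nb_fit`: mu, size (r), log_likelihood, n,
#'   converged, poisson_limit.
#' @export
fit_negative_binomial <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 30) {
    stop_with_class("need at least 30 observations", "nb_fit_degenerate")
  }
  if (stats::var(counts) == 0) {
    stop_with_class("constant counts", "nb_fit_degenerate")
  }
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- mean(counts); v <- stats::var(counts)
  loglik <- function(log_r) {
    sum(stats::dnbinom(counts, mu = m, size = exp(log_r), log = TRUE))
  }
  if (v <= m) {
    r <- 1e8
    return(structure(list(mu = m, size = r,
                          log_likelihood = loglik(log(r)), n = length(counts),
                          converged = TRUE, poisson_limit = TRUE),
                     class = "nb_fit"))
  }
  r0 <- m^2 / (v - m)
  opt <- stats::optim(log(r0), loglik, method = "Brent",
                      lower = log(r0) - 15, upper = log(r0) + 15,
                      control = list(fnscale = -1, reltol = 1e-12))
  structure(list(mu = m, size = exp(opt$par),
                 log_likelihood = opt$value, n = length(counts),
                 converged = opt$convergence == 0, poisson_limit = FALSE),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "nb_fit: mu = %.4g, size r = %.4g (n = %d, logLik = %.2f)%s%s\n",
    x$mu, x$size, x$n, x$log_likelihood,
    if (x$poisson_limit) " [Poisson limit]" else "",
    if (!x$converged) " [NOT converged]" else ""))
  invisible(x)
}

#' Split per-gene count distributions by total-count stratum
#'
#' Crowding diagnostic: partitions cells into a high stratum
#' (`total > total_threshold`) and a low stratum (`total <= threshold`) and
#' returns each requested gene's counts per stratum. Under crowding, the
#' high stratum's detected counts for abundant genes fall below truth while
#' the low stratum is unaffected.
#'
#' @param counts cells x genes count matrix.
#' @param genes genes to report (subset of columns).
#' @param total_threshold stratum boundary on per-cell totals (default
#'   100).
#' @return list with `high` and `low`, each a named list of count vectors
#'   per gene (possibly empty), plus `n_high`, `n_low`.
#' @export
crowding_split <- function(counts, genes, total_threshold = 100) {
  counts <- as.matrix(counts)
  stopifnot(all(genes %in% colnames(counts)))
  totals <- rowSums(counts)
  hi <- totals > total_threshold
  list(high = lapply(stats::setNames(genes, genes),
                     function(g) counts[hi, g]),
       low = lapply(stats::setNames(genes, genes),
                    function(g) counts[!hi, g]),
       n_high = sum(hi), n_low = sum(!hi))
}

#' Top genes by median count among nonzero cells
#'
#' Ranks genes by the median of their counts across cells with nonzero
#' counts (genes never detected rank last with median 0); ties break by
#' gene name order.
#'
#' @param counts cells x genes count matrix.
#' @param k number of genes to return.
#' @return character vector of `k` gene names.
#' @export
top_abundant_genes <- function(counts, k) {
  stopifnot(k >= 1)
  counts <- as.matrix(counts)
  med <- apply(counts, 2, function(v) {
    v <- v[v > 0]
    if (length(v)) stats::median(v) else 0
  })
  ord <- order(-med, colnames(counts))
  colnames(counts)[ord][seq_len(min(k, ncol(counts)))]
}

#' Normalize a count matrix for clustering
#'
#' The standard single-cell recipe: scale each cell to a total of 10,000
#' counts, transform elementwise with `ln(1 + x)`, then centre and scale
#' each gene to zero mean and unit variance (population SD, n denominator).
#' Genes with zero variance map to all-zero columns.
#'
#' @param counts cells x genes count matrix with no all-zero cells.
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return real-valued matrix, same dimensions and dimnames.
#' @export
normalize_for_clustering <- function(counts, target_sum = 1e4) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop_with_class("all-zero cell encountered", "normalize_zero_cell")
  }
  x <- counts * (target_sum / totals)
  x <- log1p(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(x^2) - mu^2)  # population SD
  x <- sweep(x, 2, mu)
  nz <- sdev > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sdev[nz], "/")
  x[, !nz] <- 0
  x
}
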