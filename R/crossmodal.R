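## Cross-modality similarity and annotation comparison.
##
## The diagnostic for systematic profile differences between modalities:
## for each query cell, the mean cosine similarity to every reference cell
## of a given label, on the full panel or a marker subset. Also the
## row-normalized annotation confusion matrix and label composition tables.

#' Marker-gene presets for the worked similarity cases
#'
#' Named marker subsets: `"podocyte"` (Wt1, Actn4, Synpo, Dag1, Foxc1,
#' Podxl, Mme) and `"periportal_hepatocyte"` (Cyp2f2, Pck1, Hal, Cdh1).
#'
#' @param name preset name.
#' @return character vector of gene names.
#' @export
marker_preset <- function(name = c("podocyte", "periportal_hepatocyte")) {
  name <- match.arg(name)
  switch(name,
         podocyte = c("Wt1", "Actn4", "Synpo", "Dag1", "Foxc1", "Podxl",
                      "Mme"),
         periportal_hepatocyte = c("Cyp2f2", "Pck1", "Hal", "Cdh1"))
}

#' Mean cosine similarity of query cells against reference label groups
#'
#' For each query cell and each target reference label, computes the mean
#' over all reference cells carrying that label of the cosine similarity
#' `cos(q, r) = (q . r) / (|q| |r|)`, restricted to the selected genes.
#' Zero-norm vectors (cells expressing none of the selected genes)
#' contribute similarity 0; their count is attached as attribute
#' `n_zero_norm` and reported with a warning.
#'
#' Similarity defaults to raw counts; cosine similarity is invariant to
#' per-cell scaling, so total-count differences between modalities do not
#' affect it.
#'
#' @param query query cells x genes matrix (e.g. imaging modality).
#' @param reference reference cells x genes matrix (e.g. scRNA-seq).
#' @param reference_labels named character vector, label per reference
#'   cell (names = reference rownames, or positional).
#' @param target_labels labels to compare against (default: all reference
#'   labels).
#' @param genes gene subset (default: all shared genes).
#' @return numeric matrix, query cells x target labels, of mean cosine
#'   similarities in [0, 1] for non-negative data.
#' @export
mean_cosine_similarity <- function(query, reference, reference_labels,
                                   target_labels = NULL, genes = NULL) {
  query <- as.matrix(query); reference <- as.matrix(reference)
  if (is.null(genes)) {
    genes <- intersect(colnames(query), colnames(reference))
  }
  missing_q <- setdiff(genes, colnames(query))
  missing_r <- setdiff(genes, colnames(reference))
  if (!length(genes) || length(missing_q) || length(missing_r)) {
    stop_with_class("empty or unmatched gene subset", "cosine_gene_error")
  }
  if (length(reference_labels) != nrow(reference)) {
    stop_with_class("one label per reference cell required",
                    "cosine_label_error")
  }
  if (is.null(target_labels)) target_labels <- sort(unique(reference_labels))
  absent <- setdiff(target_labels, reference_labels)
  if (length(absent)) {
    stop_with_class(sprintf("target labels absent from reference: %s",
                            paste(absent, collapse = ", ")),
                    "cosine_label_error")
  }

  q <- query[, genes, drop = FALSE]
  r <- reference[, genes, drop = FALSE]
  unit_rows <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    zero <- nrm == 0
    nrm[zero] <- 1  # zero-norm rows stay all-zero -> similarity 0
    list(m = m / nrm, n_zero = sum(zero))
  }
  qu <- unit_rows(q); ru <- unit_rows(r)
  n_zero <- qu$n_zero + ru$n_zero
  if (n_zero > 0) {
    warning(sprintf(
      "%d zero-norm cells on the selected genes contribute similarity 0",
      n_zero))
  }
  sim <- qu$m %*% t(ru$m)  # query x reference cosine matrix
  out <- vapply(target_labels, function(lab) {
    rowMeans(sim[, reference_labels == lab, drop = FALSE])
  }, numeric(nrow(q)))
  out <- matrix(out, nrow = nrow(q),
                dimnames = list(rownames(q), target_labels))
  attr(out, "n_zero_norm") <- n_zero
  out
}

#' Row-normalized annotation confusion matrix
#'
#' Entry (i, j) is the fraction of cells manually annotated with label i
#' that were predicted with label j. Rows and columns span the sorted union
#' vocabulary of the two labelings; a row whose manual label has no cells
#' is emitted as `NA` (not zeros). Every populated row sums to 1 exactly.
#'
#' @param manual named character vector: manual label per cell id.
#' @param predicted named character vector: predicted label per cell id;
#'   must cover the same cell ids.
#' @return numeric matrix, manual labels x predicted labels.
#' @export
confusion_matrix <- function(manual, predicted) {
  stopifnot(!is.null(names(manual)), !is.null(names(predicted)))
  if (!setequal(names(manual), names(predicted))) {
    stop_with_class("manual and predicted label sets cover different cells",
                    "confusion_id_mismatch")
  }
  predicted <- predicted[names(manual)]
  vocab <- sort(union(unique(manual), unique(predicted)))
  tab <- table(factor(manual, levels = vocab),
               factor(predicted, levels = vocab))
  m <- matrix(as.numeric(tab), nrow = length(vocab),
              dimnames = list(manual = vocab, predicted = vocab))
  rs <- rowSums(m)
  out <- m / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Label composition of a dataset
#'
#' @param labels character vector of cell-type labels (one per cell).
#' @return named numeric vector of per-label fractions, summing to 1,
#'   sorted by label.
#' @export
label_frequencies <- function(labels) {
  if (!length(labels)) {
    stop_with_class("empty label set", "labels_empty")
  }
  tab <- table(labels)
  stats::setNames(as.numeric(tab) / length(labels), names(tab))
}
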