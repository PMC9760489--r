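## Combinatorial barcode codebooks.
##
## Imaging-based multiplexing reads each RNA species as a fixed-length binary
## barcode; error robustness comes from keeping every pair of codewords at a
## minimum Hamming distance (the classic scheme uses constant weight 4 and
## minimum distance 4, so any single bit flip is detectable and correctable).

#' Generate a constant-weight, minimum-distance binary codebook
#'
#' Builds a set of binary codewords of length `n_bits`, each with exactly
#' `weight` ones, such that every pair of codewords differs in at least
#' `min_distance` bits. Construction is a seeded random-order greedy pass
#' over all constant-weight words: a word is accepted iff it keeps the
#' distance guarantee against everything accepted so far. Because a single
#' greedy order can stall well below the achievable packing, up to
#' `n_restarts` independent seeded orders are tried and the largest set is
#' kept (stopping early once `n_requested` is reached). Capacity is
#' therefore reported, not guaranteed; if fewer than `n_requested`
#' codewords are achieved a warning of class
#' `"codebook_capacity_shortfall"` is raised and the best set is returned.
#'
#' @param n_bits barcode length in bits (e.g. 22).
#' @param weight number of 1-bits per codeword (e.g. 4).
#' @param min_distance minimum pairwise Hamming distance; must be even
#'   (constant-weight words always differ in an even number of bits).
#' @param n_requested number of codewords wanted.
#' @param seed integer seed controlling the greedy orders.
#' @param n_restarts greedy restarts when the first order falls short
#'   (default 32).
#' @param gene_names optional character vector of names for the codewords;
#'   defaults to `gene_001`, ...
#' @return an object of class `codebook`: a list with `n_bits`, `weight`,
#'   `min_distance` and `entries` (named character vector of bitstrings).
#' @examples
#' cb <- generate_codebook(n_bits = 16, weight = 4, min_distance = 4,
#'                         n_requested = 20, seed = 1)
#' length(cb$entries)
#' @export
generate_codebook <- function(n_bits, weight, min_distance, n_requested,
                              seed = 0L, n_restarts = 32L,
                              gene_names = NULL) {
  if (!(n_bits >= weight && weight >= 1)) {
    stop_with_class("need n_bits >= weight >= 1", "codebook_invalid_parameters")
  }
  if (min_distance < 2 || min_distance %% 2 != 0) {
    stop_with_class("min_distance must be even and >= 2",
                    "codebook_invalid_parameters")
  }
  if (n_requested < 1) {
    stop_with_class("n_requested must be >= 1", "codebook_invalid_parameters")
  }

  words <- utils::combn(n_bits, weight, simplify = FALSE)
  ## greedy accept; distance between two weight-w words = 2*(w - |overlap|)
  max_shared <- weight - min_distance / 2
  greedy_pass <- function(order_idx) {
    accepted <- list()
    for (i in order_idx) {
      w <- words[[i]]
      ok <- TRUE
      for (a in accepted) {
        if (length(intersect(w, a)) > max_shared) { ok <- FALSE; break }
      }
      if (ok) {
        accepted[[length(accepted) + 1L]] <- w
        if (length(accepted) >= n_requested) break
      }
    }
    accepted
  }

  accepted <- list()
  for (rs in seq_len(max(1L, n_restarts))) {
    order_idx <- with_seed(split_seed(seed, 1000L + rs),
                           sample.int(length(words)))
    got <- greedy_pass(order_idx)
    if (length(got) > length(accepted)) accepted <- got
    if (length(accepted) >= n_requested) break
  }

  n_got <- length(accepted)
  if (n_got < n_requested) {
    warning(structure(
      class = c("codebook_capacity_shortfall", "warning", "condition"),
      list(message = sprintf(
        "requested %d codewords but greedy packing achieved %d",
        n_requested, n_got), call = sys.call())))
  }

  bits <- vapply(accepted, function(w) {
    b <- integer(n_bits); b[w] <- 1L
    paste(b, collapse = "")
  }, character(1))

  if (is.null(gene_names)) {
    gene_names <- sprintf("gene_%03d", seq_len(n_got))
  } else {
    stopifnot(!anyDuplicated(gene_names), length(gene_names) >= n_got)
    gene_names <- gene_names[seq_len(n_got)]
  }
  names(bits) <- gene_names

  structure(list(n_bits = n_bits, weight = weight,
                 min_distance = min_distance, entries = bits),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d codewords, %d bits, weight %d, min distance %d\n",
              length(x$entries), x$n_bits, x$weight, x$min_distance))
  invisible(x)
}

#' Pairwise Hamming distances between codebook entries
#'
#' @param codebook a `codebook` object.
#' @return integer matrix of pairwise Hamming distances.
#' @export
codebook_distances <- function(codebook) {
  m <- do.call(rbind, lapply(strsplit(codebook$entries, ""),
                             function(b) as.integer(b)))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(codebook$entries),
                                        names(codebook$entries)))
  for (i in seq_len(n)) {
    d[i, ] <- as.integer(colSums(abs(t(m) - m[i, ])))
  }
  d
}

#' Filter gene-panel candidates on probe count and bulk abundance
#'
#' Panel design drops genes that cannot carry enough encoding probes
#' (fewer than `min_regions` probe target regions) or are so abundant that
#' their spots would crowd the image (bulk abundance above `max_fpkm`).
#' Boundary values are retained: `target_regions == min_regions` and
#' `fpkm == max_fpkm` pass.
#'
#' @param candidates data.frame with columns `gene`, `target_regions`,
#'   `fpkm`.
#' @param min_regions minimum probe target regions per transcript
#'   (default 30).
#' @param max_fpkm maximum bulk abundance in FPKM (default 800).
#' @return the retained rows, input order preserved. An empty result is
#'   valid.
#' @export
filter_panel_candidates <- function(candidates, min_regions = 30,
                                    max_fpkm = 800) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1,
            all(c("gene", "target_regions", "fpkm") %in% names(candidates)))
  stopifnot(all(candidates$target_regions >= 0), all(candidates$fpkm >= 0))
  keep <- candidates$target_regions >= min_regions &
    candidates$fpkm <= max_fpkm
  candidates[keep, , drop = FALSE]
}
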