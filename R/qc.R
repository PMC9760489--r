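## Cell-level quality control.
##
## Segmentation quality in imaging-based spatial data is variable: some
## boundaries are drawn over empty space between cells. QC keeps cells with
## a plausible 2D area, enough transcripts for statistics, and a high
## average-DAPI alignment score (a nucleus actually under the boundary).
## All thresholds are inclusive on the "keep" side.

#' QC configuration
#'
#' Defaults are the standard cutoffs for this kind of data: areas in
#' [200, 3000] um^2, at least 80 transcripts per cell, and an average DAPI
#' score of at least 400 camera units (the valley of the bimodal score
#' distribution separating real cells from empty-space segments).
#'
#' @param area_min,area_max cell area bounds, um^2.
#' @param min_counts minimum total transcript count per cell.
#' @param min_avg_dapi minimum average DAPI score, camera units.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(area_min = 200, area_max = 3000, min_counts = 80,
                      min_avg_dapi = 400) {
  stopifnot(area_min > 0, area_min < area_max, min_counts >= 0,
            min_avg_dapi >= 0)
  structure(list(area_min = area_min, area_max = area_max,
                 min_counts = min_counts, min_avg_dapi = min_avg_dapi),
            class = "qc_config")
}

#' Apply cell-level QC filters
#'
#' Retains cells with `area_min <= area <= area_max`,
#' `total_counts >= min_counts` and `avg_dapi >= min_avg_dapi` (all
#' inclusive). The report tallies each criterion independently: a cell
#' failing two criteria increments both counters.
#'
#' @param cells cell table with columns `area_um2`, `total_counts`,
#'   `avg_dapi` (as produced by [build_cell_table()]).
#' @param config a `qc_config`.
#' @return list with `cells` (retained rows) and `report` (class
#'   `qc_report`: n_input, n_retained, n_removed_by_area/counts/dapi,
#'   yield).
#' @export
apply_qc <- function(cells, config = qc_config()) {
  stopifnot(is.data.frame(cells),
            all(c("area_um2", "total_counts", "avg_dapi") %in% names(cells)))
  if (anyNA(cells$area_um2) || anyNA(cells$total_counts) ||
      anyNA(cells$avg_dapi)) {
    stop_with_class("QC metrics contain missing values", "qc_missing_metrics")
  }
  ok_area <- cells$area_um2 >= config$area_min &
    cells$area_um2 <= config$area_max
  ok_counts <- cells$total_counts >= config$min_counts
  ok_dapi <- cells$avg_dapi >= config$min_avg_dapi
  keep <- ok_area & ok_counts & ok_dapi
  report <- structure(list(
    n_input = nrow(cells),
    n_retained = sum(keep),
    n_removed_by_area = sum(!ok_area),
    n_removed_by_counts = sum(!ok_counts),
    n_removed_by_dapi = sum(!ok_dapi),
    yield = compute_yield(sum(keep), nrow(cells)),
    config = config), class = "qc_report")
  list(cells = cells[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d of %d cells retained (yield %.0f%%)\n",
    x$n_retained, x$n_input, 100 * x$yield))
  cat(sprintf("  failed area: %d, counts: %d, DAPI: %d (non-exclusive)\n",
              x$n_removed_by_area, x$n_removed_by_counts,
              x$n_removed_by_dapi))
  invisible(x)
}

#' QC yield
#'
#' @param n_retained cells retained.
#' @param n_input cells before filtering; must be positive.
#' @return `n_retained / n_input`.
#' @examples
#' round(100 * compute_yield(34217, 83410))   # 41
#' round(100 * compute_yield(126547, 212090)) # 60
#' @export
compute_yield <- function(n_retained, n_input) {
  if (n_input <= 0) {
    stop_with_class("n_input must be positive", "qc_empty_input")
  }
  stopifnot(n_retained >= 0, n_retained <= n_input)
  n_retained / n_input
}

#' Suggest a DAPI-score threshold from a bimodal score distribution
#'
#' Advisory helper: picks the threshold maximizing Otsu's between-class
#' variance on a 256-bin histogram of the scores. Useful when the
#' average-DAPI distribution is bimodal (real cells vs empty-space
#' segments); [apply_qc()] always uses the explicit `qc_config` value.
#'
#' @param scores numeric vector of average-DAPI scores; needs at least two
#'   distinct values.
#' @return suggested threshold (same units as `scores`), strictly between
#'   the minimum and maximum score.
#' @export
suggest_dapi_threshold <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(unique(scores)) < 2) {
    stop_with_class("need at least two distinct score values",
                    "constant_scores")
  }
  n_bins <- 256L
  rng <- range(scores)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(scores, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  ## a clean gap between modes makes the objective flat across the gap's
  ## empty bins: take the middle of the plateau, not its first bin
  plateau <- which(between >= max(between) * (1 - 1e-6))
  k <- plateau[ceiling(length(plateau) / 2)]
  breaks[k + 1L]
}

#' Transcript density per field of view
#'
#' Run-level RNA-quality metric: total detected transcripts divided by the
#' number of imaged fields of view. Correlates with tissue RNA integrity.
#'
#' @param n_transcripts total detected transcripts.
#' @param n_fov number of FOVs imaged; must be positive.
#' @return transcripts per FOV.
#' @export
transcript_density <- function(n_transcripts, n_fov) {
  if (n_fov <= 0) {
    stop_with_class("n_fov must be positive", "qc_empty_input")
  }
  stopifnot(n_transcripts >= 0)
  n_transcripts / n_fov
}

#' Check sample RNA integrity metadata against a minimum RIN
#'
#' Samples whose laboratory RNA integrity number falls below `min_rin` are
#' flagged for exclusion. RIN is supplied metadata, never computed from the
#' data.
#'
#' @param rin named numeric vector of RIN scores per sample.
#' @param min_rin exclusion threshold (default 4).
#' @return data.frame with sample, rin, excluded.
#' @export
check_rin <- function(rin, min_rin = 4) {
  stopifnot(is.numeric(rin), length(rin) >= 1, !is.null(names(rin)))
  data.frame(sample = names(rin), rin = as.numeric(rin),
             excluded = as.numeric(rin) < min_rin,
             row.names = NULL, stringsAsFactors = FALSE)
}
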