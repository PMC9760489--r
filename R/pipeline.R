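## End-to-end orchestration: simulate -> assign -> qc -> concordance ->
## crossmodal -> spatial, driven by one YAML config and one seed, with a
## manifest recording every produced file, its checksum, the stage
## parameters and wall time. Stages communicate through the on-disk
## formats, so a re-run with the same config and seed is bit-identical and
## completed stages can be skipped when their outputs' checksums match.

#' Default run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param stages character vector of stages to run, in pipeline order.
#' @param rin optional RNA-integrity number for the (single) simulated
#'   sample; samples with `rin < min_rin` are excluded up front.
#' @param min_rin RIN exclusion threshold (default 4).
#' @param tissue list of overrides for [synthetic_tissue_config()].
#' @param panel list of overrides for [synthetic_panel()].
#' @param scrna list of overrides for [generate_scrna()] (`n_cells`,
#'   `dropout_inflation`).
#' @param qc list of overrides for [qc_config()].
#' @param resume reuse stage outputs whose checksums match a previous
#'   manifest (default TRUE).
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir = "spatialconcord_run", seed = 0L,
                       stages = c("simulate", "assign", "qc", "concordance",
                                  "crossmodal", "spatial"),
                       rin = NULL, min_rin = 4,
                       tissue = list(), panel = list(), scrna = list(),
                       qc = list(), resume = TRUE) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages, rin = rin,
                 min_rin = min_rin, tissue = tissue, panel = panel,
                 scrna = scrna, qc = qc, resume = resume),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

#' Validate a run configuration
#'
#' Collects every problem, not only the first.
#'
#' @param config a `run_config`.
#' @return character vector of problems; empty when valid.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  known <- c("simulate", "assign", "qc", "concordance", "crossmodal",
             "spatial")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    problems <- c(problems, sprintf("unknown stages: %s",
                                    paste(bad, collapse = ", ")))
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      config$seed < 0) {
    problems <- c(problems, "seed must be a single non-negative integer")
  }
  if (!is.character(config$out_dir) || length(config$out_dir) != 1) {
    problems <- c(problems, "out_dir must be a single path")
  }
  if (!is.null(config$rin) &&
      (!is.numeric(config$rin) || any(config$rin < 0))) {
    problems <- c(problems, "rin must be non-negative numeric")
  }
  problems
}

## internal: checksum a set of files into manifest records
file_records <- function(paths) {
  lapply(stats::setNames(paths, basename(paths)), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
}

## internal: TRUE if every file of a previous stage record still matches
stage_is_current <- function(record) {
  if (is.null(record)) return(FALSE)
  all(vapply(record$files, function(f) {
    file.exists(f$path) && identical(unname(tools::md5sum(f$path)), f$md5)
  }, logical(1)))
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order, writing every intermediate to
#' `config$out_dir` in the package's standard formats and returning a
#' manifest. With `resume = TRUE`, stages whose recorded outputs still
#' match their checksums are skipped. If the sample's RIN is below
#' `min_rin` the sample is excluded: no stages run and the manifest carries
#' the exclusion record.
#'
#' @param config a `run_config` or the path to a YAML config file.
#' @return the manifest (list, class `run_manifest`), also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  problems <- validate_run_config(config)
  if (length(problems)) {
    stop_with_class(paste(c("invalid run config:", problems),
                          collapse = "\n  - "), "run_config_invalid")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package_version = as.character(
    utils::packageVersion("spatialconcord")),
    seed = config$seed, stages = list(), exclusions = list())
  prev_path <- file.path(out, "manifest.json")
  prev <- if (config$resume && file.exists(prev_path)) {
    try(jsonlite::fromJSON(prev_path, simplifyVector = FALSE), silent = TRUE)
  } else NULL
  if (inherits(prev, "try-error")) prev <- NULL

  if (!is.null(config$rin) && any(config$rin < config$min_rin)) {
    manifest$exclusions <- list(list(
      reason = sprintf("RIN %.2f below minimum %.2f",
                       min(config$rin), config$min_rin),
      rin = config$rin))
    message(sprintf("sample excluded: RIN %.2f < %.2f",
                    min(config$rin), config$min_rin))
    write_json_result(manifest, prev_path)
    return(structure(manifest, class = "run_manifest"))
  }

  paths <- list(
    transcripts = file.path(out, "transcripts.csv"),
    segmentation = file.path(out, "segmentation.geojson"),
    dapi = file.path(out, "dapi.tiff"),
    truth_counts = file.path(out, "truth_counts"),
    truth_labels = file.path(out, "truth_labels.csv"),
    scrna_counts = file.path(out, "scrna_counts"),
    scrna_labels = file.path(out, "scrna_labels.csv"),
    assigned = file.path(out, "transcripts_assigned.csv"),
    cells = file.path(out, "cells.csv"),
    counts = file.path(out, "cell_counts"),
    qc_cells = file.path(out, "cells_qc.csv"),
    qc_report = file.path(out, "qc_report.json"),
    concordance = file.path(out, "concordance.json"),
    gene_stats = file.path(out, "gene_stats.csv"),
    similarity = file.path(out, "similarity.csv"),
    confusion = file.path(out, "confusion.csv"),
    composition = file.path(out, "composition.csv"),
    cooccurrence = file.path(out, "cooccurrence.csv"))

  mtx_files <- function(dir) {
    file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  }

  run_stage <- function(name, outputs, params, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    old <- prev$stages[[name]]
    if (config$resume && stage_is_current(old)) {
      manifest$stages[[name]] <<- old
      message(sprintf("stage %s: outputs current, skipped", name))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    ok <- try(fun(), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop_with_class(sprintf("stage %s failed: %s", name,
                              attr(ok, "condition")$message),
                      "stage_failure")
    }
    manifest$stages[[name]] <<- list(
      params = params,
      files = file_records(unlist(outputs)),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("stage %s: done", name))
  }

  tissue_args <- config$tissue
  tissue_args$seed <- split_seed(config$seed, "tissue")
  tcfg <- do.call(synthetic_tissue_config, tissue_args)
  dapi_px <- tcfg$dapi$pixel_size
  panel_args <- config$panel
  panel_args$seed <- split_seed(config$seed, "panel")
  panel <- do.call(synthetic_panel, panel_args)

  run_stage("simulate",
            c(paths[c("transcripts", "segmentation", "dapi", "truth_labels",
                      "scrna_labels")],
              mtx_files(paths$truth_counts), mtx_files(paths$scrna_counts)),
            params = list(seed = tcfg$seed, n_cells = tcfg$n_cells),
            fun = function() {
    tissue <- generate_tissue(panel, tcfg)
    write_transcripts_csv(tissue$transcripts, paths$transcripts)
    write_segmentation_geojson(tissue$segmentation, paths$segmentation)
    write_dapi_tiff(tissue$dapi, paths$dapi)
    write_count_matrix(tissue$truth$counts_detected, paths$truth_counts)
    good <- !tissue$truth$cells$is_bad_segment
    write_labels_csv(stats::setNames(tissue$truth$cells$type[good],
                                     tissue$truth$cells$cell_id[good]),
                     paths$truth_labels)
    scrna_args <- config$scrna
    scrna_args$panel <- panel
    if (is.null(scrna_args$n_cells)) scrna_args$n_cells <- 2000
    scrna_args$seed <- split_seed(config$seed, "scrna")
    sc <- do.call(generate_scrna, scrna_args)
    write_count_matrix(sc$counts, paths$scrna_counts)
    write_labels_csv(sc$labels, paths$scrna_labels)
  })

  run_stage("assign",
            c(paths[c("assigned", "cells")], mtx_files(paths$counts)),
            params = list(pixel_size = dapi_px),
            fun = function() {
    tx <- read_transcripts_csv(paths$transcripts)
    seg <- read_segmentation_geojson(paths$segmentation)
    dapi <- read_dapi_tiff(paths$dapi, pixel_size = dapi_px)
    asg <- assign_transcripts(tx, seg)
    write_transcripts_csv(asg, paths$assigned)
    ct <- build_cell_table(asg, seg, dapi, genes = panel$genes)
    write_cells_csv(ct$cells, paths$cells)
    write_count_matrix(ct$counts, paths$counts)
  })

  qcfg <- do.call(qc_config, config$qc)
  run_stage("qc", paths[c("qc_cells", "qc_report")],
            params = unclass(qcfg),
            fun = function() {
    cells <- read_cells_csv(paths$cells)
    res <- apply_qc(cells, qcfg)
    write_cells_csv(res$cells, paths$qc_cells)
    write_json_result(unclass(res$report)[c(
      "n_input", "n_retained", "n_removed_by_area", "n_removed_by_counts",
      "n_removed_by_dapi", "yield")], paths$qc_report)
  })

  run_stage("concordance", paths[c("concordance", "gene_stats")],
            params = list(), fun = function() {
    counts <- read_count_matrix(paths$counts)
    keep <- read_cells_csv(paths$qc_cells)$cell_id
    counts <- counts[rownames(counts) %in% keep, , drop = FALSE]
    sc <- read_count_matrix(paths$scrna_counts)
    panel_size <- length(panel$genes)
    bulk <- log_correlation(bulk_gene_totals(counts),
                            bulk_gene_totals(sc))
    summary <- list(
      n_cells_merfish = nrow(counts), n_cells_scrna = nrow(sc),
      bulk_log_correlation_r = bulk$r,
      median_dropout_merfish = stats::median(
        dropout_rates(counts, panel_size)),
      median_dropout_scrna = stats::median(dropout_rates(sc, panel_size)),
      mean_detection_fraction_merfish = mean(detection_fractions(counts)),
      mean_detection_fraction_scrna = mean(detection_fractions(sc)))
    write_json_result(summary, paths$concordance)
    gm <- nonzero_gene_means(counts, min_cells = 50)
    gm_sc <- nonzero_gene_means(sc, min_cells = 50)
    stats_df <- data.frame(gene = gm$gene,
                           merfish_mean = gm$mean, merfish_sem = gm$sem,
                           merfish_n_nonzero = gm$n_nonzero,
                           scrna_mean = gm_sc$mean, scrna_sem = gm_sc$sem,
                           scrna_n_nonzero = gm_sc$n_nonzero)
    utils::write.csv(stats_df, paths$gene_stats, row.names = FALSE)
  })

  run_stage("crossmodal",
            paths[c("similarity", "confusion", "composition")],
            params = list(), fun = function() {
    counts <- read_count_matrix(paths$counts)
    truth <- read_labels_csv(paths$truth_labels)
    keep <- intersect(read_cells_csv(paths$qc_cells)$cell_id, names(truth))
    counts <- counts[keep, , drop = FALSE]
    truth <- truth[keep]
    sc <- read_count_matrix(paths$scrna_counts)
    sc_labels <- read_labels_csv(paths$scrna_labels)
    sim <- mean_cosine_similarity(counts, sc, sc_labels[rownames(sc)])
    long <- data.frame(cell_id = rep(rownames(sim), ncol(sim)),
                       reference_label = rep(colnames(sim),
                                             each = nrow(sim)),
                       mean_cosine = as.vector(sim))
    utils::write.csv(long, paths$similarity, row.names = FALSE)
    predicted <- colnames(sim)[max.col(sim, ties.method = "first")]
    names(predicted) <- rownames(sim)
    cm <- confusion_matrix(truth, predicted)
    utils::write.csv(cbind(manual = rownames(cm), as.data.frame(cm)),
                     paths$confusion, row.names = FALSE)
    comp <- rbind(
      data.frame(modality = "merfish",
                 label = names(label_frequencies(truth)),
                 fraction = as.numeric(label_frequencies(truth))),
      data.frame(modality = "scrna",
                 label = names(label_frequencies(sc_labels)),
                 fraction = as.numeric(label_frequencies(sc_labels))))
    utils::write.csv(comp, paths$composition, row.names = FALSE)
  })

  run_stage("spatial", paths["cooccurrence"], params = list(),
            fun = function() {
    cells <- read_cells_csv(paths$qc_cells)
    truth <- read_labels_csv(paths$truth_labels)
    cells$label <- unname(truth[cells$cell_id])
    cells <- cells[!is.na(cells$label), ]
    res <- cooccurrence_ratio(cells,
                              bin_edges = seq(25, 500, by = 25))
    utils::write.csv(cooccurrence_long(res), paths$cooccurrence,
                     row.names = FALSE)
  })

  write_json_result(manifest, prev_path)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %s, %d stages, %d exclusions\n",
              format(x$seed), length(x$stages), length(x$exclusions)))
  for (s in names(x$stages)) {
    cat(sprintf("  %s: %d files (%.2fs)\n", s, length(x$stages[[s]]$files),
                as.numeric(x$stages[[s]]$wall_time_s)))
  }
  invisible(x)
}
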