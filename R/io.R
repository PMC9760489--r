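## Format adapters shared by all stages: transcripts CSV, segmentation
## GeoJSON, DAPI TIFF, Matrix Market count triplets, label CSV, result
## JSON. Round-trips preserve integer data exactly and coordinates to full
## double precision.

#' Write / read a decoded transcript table as CSV
#'
#' Columns `gene,x,y,z,fov,cell_id`; an empty `cell_id` field means
#' unassigned. Coordinates are written with 17 significant digits so the
#' doubles round-trip exactly.
#'
#' @param transcripts transcript data.frame.
#' @param path file path.
#' @return `path`, invisibly (writer) / the transcript data.frame
#'   (reader).
#' @export
write_transcripts_csv <- function(transcripts, path) {
  stopifnot(all(c("gene", "x", "y", "z") %in% names(transcripts)))
  df <- data.frame(
    gene = transcripts$gene,
    x = sprintf("%.17g", transcripts$x),
    y = sprintf("%.17g", transcripts$y),
    z = transcripts$z,
    fov = if ("fov" %in% names(transcripts)) transcripts$fov else 1L,
    cell_id = if ("cell_id" %in% names(transcripts)) {
      ifelse(is.na(transcripts$cell_id), "", transcripts$cell_id)
    } else "",
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transcripts_csv
#' @export
read_transcripts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(gene = "character", x = "numeric",
                                       y = "numeric", z = "integer",
                                       fov = "integer",
                                       cell_id = "character"))
  if (!all(c("gene", "x", "y", "z") %in% names(df))) {
    stop_with_class(sprintf("malformed transcript CSV %s: need gene,x,y,z",
                            path), "io_malformed")
  }
  df$cell_id[df$cell_id == ""] <- NA_character_
  df
}

#' Write / read a segmentation set as GeoJSON
#'
#' One `Feature` per cell with a closed `Polygon` ring (first vertex
#' repeated last) in um coordinates and property `cell_id`; z-stack
#' metadata (`n_z`, `median_z_index`) travels as foreign members of the
#' `FeatureCollection`. The reader accepts open or closed rings and
#' normalizes closure.
#'
#' @param segmentation a `segmentation_set`.
#' @param path file path.
#' @return `path`, invisibly (writer) / a `segmentation_set` (reader).
#' @export
write_segmentation_geojson <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "segmentation_set"))
  features <- lapply(names(segmentation$polygons), function(id) {
    p <- segmentation$polygons[[id]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(cell_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  obj <- list(type = "FeatureCollection",
              n_z = segmentation$n_z,
              median_z_index = segmentation$median_z_index,
              features = features)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_segmentation_geojson
#' @export
read_segmentation_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop_with_class(sprintf("%s: not a GeoJSON FeatureCollection", path),
                    "io_malformed")
  }
  polys <- list()
  for (k in seq_along(obj$features)) {
    f <- obj$features[[k]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop_with_class(sprintf("%s: feature %d is not a Polygon", path, k),
                      "io_malformed")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    id <- f$properties$cell_id
    if (is.null(id)) {
      stop_with_class(sprintf("%s: feature %d lacks cell_id", path, k),
                      "io_malformed")
    }
    polys[[id]] <- ring
  }
  n_z <- if (!is.null(obj$n_z)) obj$n_z else 7L
  med <- if (!is.null(obj$median_z_index)) obj$median_z_index else (n_z - 1) %/% 2
  segmentation_set(polys, n_z = n_z, median_z_index = med)
}

#' Write / read a DAPI raster as single-channel 16-bit TIFF
#'
#' Intensities are stored as 16-bit samples; values must lie in
#' [0, 65535]. The pixel size is not stored in the TIFF and must be carried
#' by the run configuration.
#'
#' @param dapi a `dapi_image`.
#' @param path file path.
#' @param pixel_size um/px (reader).
#' @param origin raster origin in um (reader).
#' @return `path`, invisibly (writer) / a `dapi_image` (reader).
#' @export
write_dapi_tiff <- function(dapi, path) {
  stopifnot(inherits(dapi, "dapi_image"),
            all(dapi$raster >= 0), all(dapi$raster <= 65535))
  tiff::writeTIFF(dapi$raster / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_dapi_tiff
#' @export
read_dapi_tiff <- function(path, pixel_size, origin = c(0, 0)) {
  r <- tiff::readTIFF(path)
  if (length(dim(r)) == 3) r <- r[, , 1]
  dapi_image(round(r * 65535), pixel_size = pixel_size, origin = origin)
}

#' Write / read a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx` (coordinate integer dialect, 1-based; rows are
#' cells, columns genes), `barcodes.tsv` (one cell id per line, order
#' defining matrix rows) and `features.tsv` (one gene per line, defining
#' columns) under `dir`.
#'
#' @param counts cells x genes integer matrix with dimnames.
#' @param dir directory (created if needed).
#' @return `dir`, invisibly (writer) / the dense integer matrix with
#'   dimnames (reader).
#' @export
write_count_matrix <- function(counts, dir) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ## coordinate *integer* dialect (Matrix::writeMM only emits "real");
  ## read back with Matrix::readMM, which accepts it
  nz <- which(counts != 0, arr.ind = TRUE)
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(nz))),
             con)
  if (nrow(nz)) {
    writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2],
                       as.integer(counts[nz])), con)
  }
  close(con)
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) {
    stop_with_class(sprintf("missing %s", mtx), "io_malformed")
  }
  m <- as.matrix(Matrix::readMM(mtx))
  storage.mode(m) <- "integer"
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  if (nrow(m) != length(barcodes) || ncol(m) != length(features)) {
    stop_with_class(sprintf(
      "%s: matrix is %d x %d but %d barcodes / %d features", dir,
      nrow(m), ncol(m), length(barcodes), length(features)), "io_malformed")
  }
  dimnames(m) <- list(barcodes, features)
  m
}

#' Write / read a cell label table as CSV
#'
#' Columns `cell_id,label`.
#'
#' @param labels named character vector (names = cell ids).
#' @param path file path.
#' @return `path`, invisibly (writer) / named character vector (reader).
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  utils::write.csv(data.frame(cell_id = names(labels),
                              label = as.character(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("cell_id", "label") %in% names(df))) {
    stop_with_class(sprintf("%s: need columns cell_id,label", path),
                    "io_malformed")
  }
  stats::setNames(df$label, df$cell_id)
}

#' Write / read a cell metadata table as CSV
#'
#' @param cells cell table (data.frame from [build_cell_table()], possibly
#'   with extra columns).
#' @param path file path.
#' @return `path`, invisibly (writer) / the data.frame (reader).
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a result object as JSON
#'
#' @param x a list of results (scalars unboxed).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}
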