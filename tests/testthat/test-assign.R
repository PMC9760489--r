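unit_square <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))

test_that("point-in-polygon handles interior, exterior and boundary points", {
  expect_true(points_in_polygon(c(0.5, 0.5), unit_square))
  expect_false(points_in_polygon(c(1.5, 0.5), unit_square))
  # boundary inclusive by convention
  expect_true(points_in_polygon(c(1, 0.5), unit_square))
  expect_true(points_in_polygon(c(0, 0), unit_square))
  # degenerate polygons are structured errors
  expect_error(points_in_polygon(c(0, 0), unit_square[1:2, ]),
               class = "degenerate_polygon")
  expect_error(points_in_polygon(c(0, 0),
                                 cbind(c(0, 1, 2), c(0, 1, 2))),
               class = "degenerate_polygon")
})

test_that("point-in-polygon matches winding-number oracle on random 12-gons", {
  set.seed(101)
  ang <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(10 + runif(12, 2, 5) * cos(ang),
                8 + runif(12, 2, 5) * sin(ang))
  pts <- cbind(runif(1000, 4, 16), runif(1000, 2, 14))
  got <- points_in_polygon(pts, poly)
  want <- vapply(seq_len(nrow(pts)), function(i)
    oracle_point_in_polygon(pts[i, 1], pts[i, 2], poly), logical(1))
  # random continuous points are almost surely off the boundary, where the
  # two formulations must agree exactly
  expect_identical(got, want)

  # independent library cross-check on the same instance
  if (requireNamespace("mgcv", quietly = TRUE)) {
    expect_identical(got, as.logical(mgcv::in.out(
      rbind(poly, poly[1, ]), pts)))
  }
})

test_that("shoelace area matches known shapes and is invariant to orientation and translation", {
  expect_equal(polygon_area(unit_square), 1.0)
  rect <- cbind(c(0, 50, 50, 0), c(0, 0, 20, 20))
  expect_equal(polygon_area(rect), 1000)
  # orientation reversal and translation
  expect_equal(polygon_area(rect[4:1, ]), 1000)
  expect_equal(polygon_area(sweep(rect, 2, c(123.4, -56.7), "+")), 1000)

  # rasterization oracle on a random simple polygon
  set.seed(7)
  ang <- sort(runif(9, 0, 2 * pi))
  poly <- cbind(6 + runif(9, 2, 4) * cos(ang), 6 + runif(9, 2, 4) * sin(ang))
  h <- 0.01
  gx <- seq(0, 12, by = h); gy <- seq(0, 12, by = h)
  grid <- cbind(rep(gx + h / 2, times = length(gy)),
                rep(gy + h / 2, each = length(gx)))
  raster_area <- sum(points_in_polygon(grid, poly)) * h^2
  expect_lt(abs(polygon_area(poly) - raster_area) / polygon_area(poly),
            0.005)
})

test_that("average DAPI is the mean over in-polygon pixel centres", {
  # uniform raster: average equals the constant
  img <- dapi_image(matrix(500, 20, 20), pixel_size = 1)
  expect_equal(compute_average_dapi(unit_square * 10, img), 500)

  # polygon covering exactly two pixel centres with values 100 and 300
  r <- matrix(0, 4, 4); r[2, 2] <- 100; r[2, 3] <- 300
  img2 <- dapi_image(r, pixel_size = 1)
  # pixel centres (1.5, 1.5) and (2.5, 1.5); thin box around both
  box <- cbind(c(1.2, 2.8, 2.8, 1.2), c(1.2, 1.2, 1.8, 1.8))
  expect_equal(compute_average_dapi(box, img2), 200)

  # brute-force enumeration oracle on a random raster and polygon
  set.seed(21)
  r3 <- matrix(runif(30 * 40, 0, 1000), 30, 40)
  img3 <- dapi_image(r3, pixel_size = 0.5)
  ang <- sort(runif(8, 0, 2 * pi))
  poly <- cbind(9 + runif(8, 2, 4) * cos(ang), 7 + runif(8, 2, 4) * sin(ang))
  acc <- c(); n_in <- 0
  for (i in 1:30) for (j in 1:40) {
    cx <- (j - 0.5) * 0.5; cy <- (i - 0.5) * 0.5
    if (oracle_point_in_polygon(cx, cy, poly)) {
      acc <- c(acc, r3[i, j]); n_in <- n_in + 1
    }
  }
  expect_equal(compute_average_dapi(poly, img3), mean(acc))

  # polygon with no pixel centres is a structured error
  tiny <- cbind(c(0.9, 1.1, 1.0), c(0.9, 0.9, 1.1)) + 0.25
  expect_error(compute_average_dapi(tiny, dapi_image(matrix(1, 2, 2), 2)),
               class = "empty_pixel_set")
})

test_that("transcript assignment uses the projected median-z boundary with smallest-area tie-break", {
  polyA <- unit_square * 10                       # area 100
  polyB <- cbind(c(2, 6, 6, 2), c(2, 2, 6, 6))    # area 16, inside A
  seg <- segmentation_set(list(A = polyA, B = polyB), n_z = 7)
  tx <- data.frame(gene = "g",
                   x = c(5, 1, 20), y = c(5, 1, 20),
                   z = c(0L, 6L, 3L))
  out <- assign_transcripts(tx, seg)
  # z is ignored; point in both polygons goes to the smaller B
  expect_equal(out$cell_id, c("B", "A", NA))
  expect_equal(nrow(out), nrow(tx))
  # idempotent
  expect_identical(assign_transcripts(out, seg), out)
  # conservation
  expect_equal(sum(!is.na(out$cell_id)) + sum(is.na(out$cell_id)), nrow(tx))
})

test_that("assignment reproduces generator ground truth when polygons capture everything", {
  panel <- small_panel()
  tis <- generate_tissue(panel, small_tissue_config(seed = 3))
  asg <- assign_transcripts(tis$transcripts, tis$segmentation)
  expect_identical(asg$cell_id, tis$truth$transcript_source)
})

test_that("cell table preserves counts exactly and keeps zero-count cells", {
  panel <- small_panel()
  tis <- generate_tissue(panel, small_tissue_config(seed = 9,
                                                    bad_segment_fraction = 0.1))
  asg <- assign_transcripts(tis$transcripts, tis$segmentation)
  ct <- build_cell_table(asg, tis$segmentation, tis$dapi,
                         genes = panel$genes)
  # one row per segmented cell, bad segments (zero counts) included
  expect_equal(nrow(ct$cells), length(tis$segmentation$polygons))
  bad <- tis$truth$cells$cell_id[tis$truth$cells$is_bad_segment]
  expect_true(all(ct$cells$total_counts[ct$cells$cell_id %in% bad] == 0))
  # grand total equals number of assigned transcripts, exactly
  expect_identical(sum(ct$counts), sum(!is.na(asg$cell_id)))
  # end-to-end closure against ground truth
  td <- tis$truth$counts_detected
  expect_identical(ct$counts[rownames(td), colnames(td)], td)
  # unknown ids are structured errors
  bad_tx <- asg; bad_tx$cell_id[1] <- "nope"
  expect_error(build_cell_table(bad_tx, tis$segmentation, NULL),
               class = "unknown_cell_id")
})
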