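test_that("mean cosine similarity matches hand arithmetic and a double-loop oracle", {
  ref <- rbind(r1 = c(1, 0), r2 = c(0, 1), r3 = c(1, 0))
  colnames(ref) <- c("gA", "gB")
  q <- rbind(q1 = c(1, 0)); colnames(q) <- colnames(ref)
  labs <- c(r1 = "L", r2 = "L", r3 = "M")

  sim <- mean_cosine_similarity(q, ref, labs)
  # label L holds (1,0) and (0,1): mean = (1 + 0)/2
  expect_equal(sim["q1", "L"], 0.5)
  # label M holds the query itself
  expect_equal(sim["q1", "M"], 1.0)

  # brute-force double loop on random matrices
  set.seed(14)
  Q <- matrix(rexp(8 * 6), 8, 6,
              dimnames = list(sprintf("q%d", 1:8), sprintf("g%d", 1:6)))
  R <- matrix(rexp(10 * 6), 10, 6,
              dimnames = list(sprintf("r%d", 1:10), colnames(Q)))
  rl <- rep(c("A", "B"), 5)
  got <- mean_cosine_similarity(Q, R, rl)
  for (i in 1:8) for (lab in c("A", "B")) {
    vals <- vapply(which(rl == lab), function(j)
      sum(Q[i, ] * R[j, ]) / sqrt(sum(Q[i, ]^2) * sum(R[j, ]^2)),
      numeric(1))
    expect_equal(got[i, lab], mean(vals), tolerance = 1e-10)
  }
  expect_true(all(got >= 0 & got <= 1))

  # invariance to positive per-cell scaling
  sc <- diag(runif(8, 0.1, 10)) %*% Q
  dimnames(sc) <- dimnames(Q)
  expect_equal(mean_cosine_similarity(sc, R, rl), got, tolerance = 1e-10)

  # zero-norm convention: similarity 0, with a warning
  Q0 <- rbind(Q, q0 = 0)
  expect_warning(s0 <- mean_cosine_similarity(Q0, R, rl))
  expect_true(all(s0["q0", ] == 0))

  # structured errors
  expect_error(mean_cosine_similarity(Q, R, rl, genes = "missing"),
               class = "cosine_gene_error")
  expect_error(mean_cosine_similarity(Q, R, rl, target_labels = "Z"),
               class = "cosine_label_error")
})

test_that("well-separated types are most similar to their own reference label", {
  panel <- small_panel()
  sc_ref <- generate_scrna(panel, 400, dropout_inflation = 0.3, seed = 41)
  sc_query <- generate_scrna(panel, 300, dropout_inflation = 0, seed = 42)
  sim <- mean_cosine_similarity(sc_query$counts, sc_ref$counts,
                                sc_ref$labels)
  best <- colnames(sim)[max.col(sim, ties.method = "first")]
  expect_gt(mean(best == sc_query$labels), 0.90)
})

test_that("a profile shifted toward another type flips the similarity ordering", {
  panel <- small_panel()
  types <- rownames(panel$type_means)
  ref <- generate_scrna(panel, 400, dropout_inflation = 0, seed = 51)
  # queries labeled as type 1 but drawn from type 2's profile (the
  # podocyte-vs-endothelial situation): similarity must favor type 2
  shifted <- panel
  shifted$type_means[types[1], ] <- panel$type_means[types[2], ]
  q <- generate_scrna(shifted, 200,
                      type_proportions = setNames(
                        c(1, rep(0, length(types) - 1)), types),
                      dropout_inflation = 0, seed = 52)
  sim <- mean_cosine_similarity(q$counts, ref$counts, ref$labels,
                                target_labels = types[1:2])
  expect_gt(mean(sim[, types[2]] > sim[, types[1]]), 0.9)
})

test_that("confusion matrix is the row-normalized cross-tabulation with NA empty rows", {
  ids <- sprintf("c%d", 1:4)
  manual <- setNames(c("A", "A", "B", "B"), ids)
  predicted <- setNames(c("A", "B", "B", "B"), ids)
  cm <- confusion_matrix(manual, predicted)
  expect_equal(cm["A", ], c(A = 0.5, B = 0.5))
  expect_equal(cm["B", ], c(A = 0.0, B = 1.0))
  expect_true(all(abs(rowSums(cm) - 1) < 1e-12))

  # identity on perfect agreement
  cm_id <- confusion_matrix(manual, manual)
  expect_equal(unname(cm_id), diag(2))

  # label only present in predictions: its manual row is NA, not zeros
  pred2 <- setNames(c("A", "C", "B", "B"), ids)
  cm2 <- confusion_matrix(manual, pred2)
  expect_true(all(is.na(cm2["C", ])))
  expect_equal(sum(cm2["A", ]), 1)

  expect_error(confusion_matrix(manual, predicted[1:3]),
               class = "confusion_id_mismatch")
})

test_that("confusion rows under label permutation approach the marginal frequencies", {
  set.seed(61)
  ids <- sprintf("c%05d", 1:4000)
  labs <- setNames(sample(c("A", "B", "C"), 4000, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)), ids)
  perm <- setNames(sample(labs), ids)
  cm <- confusion_matrix(labs, perm)
  freq <- label_frequencies(labs)
  for (i in rownames(cm)) {
    n_i <- sum(labs == i)
    se <- sqrt(freq * (1 - freq) / n_i)
    expect_true(all(abs(cm[i, names(freq)] - freq) < 4 * se))
  }
})

test_that("label frequencies are exact tallies summing to one", {
  expect_equal(label_frequencies(c("A", "A", "B", "C")),
               c(A = 0.5, B = 0.25, C = 0.25))
  expect_equal(label_frequencies("solo"), c(solo = 1.0))
  expect_equal(sum(label_frequencies(sample(letters[1:5], 100, TRUE))), 1)
  expect_error(label_frequencies(character(0)), class = "labels_empty")
})

test_that("marker presets carry the published marker subsets", {
  expect_length(marker_preset("podocyte"), 7)
  expect_true("Wt1" %in% marker_preset("podocyte"))
  expect_equal(marker_preset("periportal_hepatocyte"),
               c("Cyp2f2", "Pck1", "Hal", "Cdh1"))
})
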