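test_that("normalization is counts-per-scale log1p and depth-invariant", {
  counts <- matrix(c(5, 0, 0, 0, 2, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  cm <- cell_matrix(counts, data.frame(cell = c("c1", "c2"),
                                       condition = "vehicle"))
  norm <- normalize_cells(cm, scale = 1e4)
  expect_equal(norm["c1", ], c(g1 = log(1 + 1e4), g2 = 0, g3 = 0))
  expect_equal(norm["c2", ],
               log(1 + 1e4 * c(g1 = 0, g2 = 2, g3 = 2) / 4))

  # doubling one cell's counts leaves its profile unchanged
  counts2 <- counts; counts2["c2", ] <- counts2["c2", ] * 2
  cm2 <- cell_matrix(counts2, cm$meta)
  expect_equal(normalize_cells(cm2)["c2", ], norm["c2", ])

  counts3 <- counts; counts3["c2", ] <- 0
  expect_error(normalize_cells(cell_matrix(counts3, cm$meta)), "c2")
})

test_that("cell_matrix validates counts and metadata alignment", {
  counts <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
  meta <- data.frame(cell = c("c2", "c1"), condition = c("t", "v"))
  cm <- cell_matrix(counts, meta)
  expect_identical(cm$meta$condition, c("v", "t"))  # reordered to counts
  expect_error(cell_matrix(counts, meta[1, , drop = FALSE]),
               "without metadata")
  expect_error(cell_matrix(counts - 2, meta), "non-negative")
  expect_error(cell_matrix(counts + 0.5, meta), "integer")
})

test_that("per-cell scores: identical cells score 0, elevated cell ranks top", {
  genes <- c("HNF1A", "MUC13", "BG1", "BG2")
  counts <- matrix(5L, nrow = 6, ncol = 4,
                   dimnames = list(paste0("c", 1:6), genes))
  meta <- data.frame(cell = paste0("c", 1:6),
                     condition = rep(c("vehicle", "treated"), 3))
  cm <- cell_matrix(counts, meta)
  sc <- cell_signature_score(cm, gene_signature("s", c("HNF1A", "MUC13")))
  expect_equal(sc$score, rep(0, 6))  # constant genes -> z = 0

  counts2 <- counts
  counts2["c3", c("HNF1A", "MUC13")] <- 50L
  sc2 <- cell_signature_score(cell_matrix(counts2, meta),
                              gene_signature("s", c("HNF1A", "MUC13")))
  expect_equal(sc2$cell[which.max(sc2$score)], "c3")
})

test_that("per-cell scores are invariant to cell and gene ordering", {
  cm <- toy_cells(n_per_cond = 6)
  sig <- gene_signature("s", c("HNF1A", "MUC13"))
  base <- cell_signature_score(cm, sig)
  perm_cells <- sample(nrow(cm$counts))
  perm_genes <- sample(ncol(cm$counts))
  cm2 <- cell_matrix(cm$counts[perm_cells, perm_genes], cm$meta)
  out <- cell_signature_score(cm2, sig)
  expect_equal(out$score[match(base$cell, out$cell)], base$score)
})

test_that("pseudobulk sums counts by condition and conserves the grand total", {
  counts <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 4,
                   dimnames = list(paste0("c", 1:4), c("g1", "g2")))
  meta <- data.frame(cell = paste0("c", 1:4),
                     condition = c("vehicle", "vehicle", "treated",
                                   "treated"))
  pb <- pseudobulk(cell_matrix(counts, meta))
  expect_equal(pb[, "vehicle"], c(g1 = 3, g2 = 11))
  expect_equal(pb[, "treated"], c(g1 = 7, g2 = 15))
  expect_equal(sum(pb), sum(counts))
  # single condition equals per-gene totals
  meta1 <- transform(meta, condition = "vehicle")
  expect_equal(pseudobulk(cell_matrix(counts, meta1))[, 1], colSums(counts))
  expect_error(pseudobulk(cell_matrix(counts, meta), "nope"), "unknown")
})

test_that("condition comparison reports shift B - A with Welch p", {
  cm <- toy_cells(n_per_cond = 10)
  sc <- cell_signature_score(cm, gene_signature("s", c("HNF1A", "MUC13")))
  res <- compare_condition_scores(sc, "s", "vehicle", "treated")
  ref <- t.test(sc$score[sc$condition == "treated"],
                sc$score[sc$condition == "vehicle"])
  expect_equal(res$p.value, ref$p.value)
  expect_equal(res$mean_diff,
               mean(sc$score[sc$condition == "treated"]) -
                 mean(sc$score[sc$condition == "vehicle"]))
  # constant shift is recovered exactly
  sc2 <- sc
  sc2$score[sc2$condition == "treated"] <-
    sc2$score[sc2$condition == "treated"] + 2.5
  expect_equal(compare_condition_scores(sc2, "s", "vehicle",
                                        "treated")$mean_diff,
               res$mean_diff + 2.5)
  expect_error(compare_condition_scores(sc[1:3, ], "s", "vehicle",
                                        "treated"), "at least 2 cells")
})

test_that("a planted two-population shift separates scores with high AUC", {
  cm <- simulate_single_cell(n_cells_per_condition = 150,
                             treatment_hnf_downscale = 2, seed = 19,
                             n_background_genes = 50)
  sc <- cell_signature_score(cm, hnf_signature())
  treated <- sc$condition == "treated"
  # AUC of the HNF score for vehicle (high) vs treated (low)
  r <- rank(sc$score)
  n1 <- sum(!treated); n2 <- sum(treated)
  auc <- (sum(r[!treated]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  expect_gt(auc, 0.9)
})
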