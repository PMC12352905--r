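test_that("log2 transform applies log2(v + pseudocount) and retags scale", {
  m <- expression_matrix(matrix(c(1, 0, 3, 7), 2, 2,
         dimnames = list(c("g1", "g2"), c("s1", "s2"))), scale = "tpm")
  lt <- log2_transform(m, pseudocount = 1)
  expect_equal(as.matrix(lt)[, "s1"], c(g1 = 1, g2 = 0))
  expect_equal(as.matrix(lt)["g1", "s2"], 2)
  expect_identical(lt$scale_tag, "log2tpm")
  expect_error(log2_transform(lt), "already")
  expect_error(log2_transform(m, pseudocount = 0), "positive")
})

test_that("matrix construction rejects duplicates and negatives with context", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("A", "a"), c("s1", "s2")))
  expect_error(expression_matrix(vals, "tpm"), "duplicate gene")
  vals2 <- matrix(c(1, -2, 3, 4), 2, 2,
                  dimnames = list(c("A", "B"), c("s1", "s2")))
  err <- expect_error(expression_matrix(vals2, "tpm"))
  expect_match(conditionMessage(err), "B")
  expect_match(conditionMessage(err), "s1")
  # negatives fine on the log scale
  expect_s3_class(expression_matrix(vals2, "log2tpm"), "expression_matrix")
})

test_that("gene z-scores match hand computation and handle constants", {
  m <- expression_matrix(matrix(c(1, 5, 2, 5, 3, 5), 2, 3,
         dimnames = list(c("g", "flat"), c("s1", "s2", "s3"))))
  expect_warning(z <- gene_zscores(m), "constant")
  expect_equal(unname(z["g", ]), c(-1, 0, 1))
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  # two samples: +- 1/sqrt(2) with sample sd
  m2 <- expression_matrix(matrix(c(0, 4), 1, 2,
          dimnames = list("g", c("a", "b"))))
  expect_equal(sort(unname(gene_zscores(m2)["g", ])),
               c(-1, 1) / sqrt(2))
  m1 <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "a")))
  expect_error(gene_zscores(m1), "2 samples")
})

test_that("non-constant z rows have mean 0 and sample sd 1", {
  m <- toy_expression(genes = paste0("g", 1:20), n_samples = 9)
  z <- gene_zscores(m)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
})

test_that("summed score adds per-gene z and records missing genes", {
  m <- expression_matrix(matrix(c(1, 4, 2, 5, 3, 6), 2, 3,
         dimnames = list(c("A", "B"), c("s1", "s2", "s3"))))
  z <- gene_zscores(m)
  st <- sum_z_score(z, gene_signature("ab", c("A", "B")))
  expect_equal(st$score, c(-2, 0, 2))
  expect_equal(st$n_genes_used, rep(2L, 3))
  expect_identical(st$missing_genes, rep("", 3))

  sig <- gene_signature("abx", c("A", "B", "GONE"))
  expect_warning(st2 <- sum_z_score(z, sig), "GONE")
  expect_equal(st2$score, st$score)
  expect_equal(st2$n_genes_used + lengths(strsplit(st2$missing_genes, ",")),
               rep(length(sig$genes), 3))
  expect_error(sum_z_score(z, sig, missing_policy = "error"), "GONE")
  expect_error(sum_z_score(z, gene_signature("none", "NOPE")), "no gene")
})

test_that("gene matching is case-insensitive after trimming", {
  m <- expression_matrix(matrix(c(1, 2, 3, 1, 5, 4), 2, 3,
         dimnames = list(c(" hnf1a ", "Muc13"), c("s1", "s2", "s3"))))
  z <- gene_zscores(m)
  st <- sum_z_score(z, gene_signature("hnf2", c("HNF1A", "MUC13")))
  expect_equal(st$n_genes_used, rep(2L, 3))
})

test_that("scores are invariant to gene-row and signature-order permutation, and to extra genes", {
  m <- toy_expression(genes = c("HNF1A", "MUC13", "SGK2", "BG1"),
                      n_samples = 6)
  sig <- gene_signature("s", c("HNF1A", "MUC13", "SGK2"))
  base <- sum_z_score(gene_zscores(m), sig)$score

  perm <- expression_matrix(as.matrix(m)[c(3, 1, 4, 2), ])
  expect_equal(sum_z_score(gene_zscores(perm), sig)$score, base)

  sig2 <- gene_signature("s2", rev(sig$genes))
  expect_equal(sum_z_score(gene_zscores(m), sig2)$score, base)

  extra <- expression_matrix(rbind(as.matrix(m),
                                   NEW = seq_len(ncol(as.matrix(m)))))
  expect_equal(sum_z_score(gene_zscores(extra), sig)$score, base)
})

test_that("raising one signature gene in one sample raises only that sample's score", {
  m <- toy_expression(genes = c("HNF1A", "MUC13", "BG1"), n_samples = 5)
  sig <- gene_signature("s", c("HNF1A", "MUC13"))
  before <- sum_z_score(gene_zscores(m), sig)$score
  v <- as.matrix(m)
  v["HNF1A", 2] <- v["HNF1A", 2] + 3
  after <- sum_z_score(gene_zscores(expression_matrix(v)), sig)$score
  expect_gt(after[2], before[2])
  expect_true(all((after - before)[-2] < (after - before)[2]))
})

test_that("stratification applies the fixed thresholds and partitions samples", {
  st <- data.frame(sample = letters[1:5], signature = "HNF",
                   score = c(12, 11.999, 0, -3, 5),
                   n_genes_used = 11L, missing_genes = "")
  out <- stratify_hnf(st)
  expect_identical(as.character(out$stratum),
                   c("High", "Intermediate", "Low", "Low", "Intermediate"))
  expect_false(anyNA(out$stratum))  # partition: exactly one label each

  two <- stratify_hnf(st, mode = "two")
  expect_identical(as.character(two$stratum),
                   c("High", "Low", "Low", "Low", "Low"))
  expect_error(stratify_hnf(st, high_threshold = 0, low_threshold = 0),
               "low_threshold < high_threshold")
  st$score[1] <- NA
  expect_error(stratify_hnf(st), "numeric")
})

test_that("score_signatures composes transform, z-scoring and scoring", {
  sc <- simulate_bulk_cohort(cohort_spec(n_background_genes = 20), seed = 5)
  tab <- score_signatures(sc$matrix, list(hnf_signature(), ar10_signature()),
                          missing_policy = "drop_warn")
  expect_setequal(unique(tab$signature), c("HNF", "AR_10_gene"))
  hand <- sum_z_score(gene_zscores(log2_transform(sc$matrix)),
                      hnf_signature())
  expect_equal(tab$score[tab$signature == "HNF"], hand$score)
})
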