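test_that("cohort spec validates its fields", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(frac_high = 0))
  expect_error(cohort_spec(p_nonresponse_high = 1.2))
  expect_error(cohort_spec(hazard_ratio_high = -1))
  expect_error(cohort_spec(censor_rate = 1))
})

test_that("simulated cohort objects satisfy downstream type invariants", {
  sc <- simulate_bulk_cohort(cohort_spec(n_background_genes = 30), seed = 2)
  expect_s3_class(sc$matrix, "expression_matrix")
  expect_identical(sc$matrix$scale_tag, "tpm")
  expect_true(all(as.matrix(sc$matrix) >= 0))
  expect_identical(names(sc$truth), sc$matrix$samples)
  expect_identical(sc$outcomes$sample, sc$matrix$samples)
  expect_true(all(sc$outcomes$response %in% c("responder", "nonresponder")))
  expect_true(all(sc$outcomes$tot_time >= 0 & sc$outcomes$os_time >= 0))
  expect_true(all(sc$outcomes$tot_event %in% 0:1))
  expect_equal(sum(sc$truth), round(0.2 * 25))
  # the 11 signature genes and the AR panel are all present
  expect_true(all(hnf_signature()$genes %in% sc$matrix$genes))
  expect_true(all(ar_signature()$genes %in% sc$matrix$genes))
})

test_that("generators are pure functions of spec and seed", {
  a <- simulate_bulk_cohort(cohort_spec(n_background_genes = 20), seed = 9)
  b <- simulate_bulk_cohort(cohort_spec(n_background_genes = 20), seed = 9)
  expect_identical(a, b)
  c1 <- simulate_single_cell(30, 2, seed = 4, n_background_genes = 10)
  c2 <- simulate_single_cell(30, 2, seed = 4, n_background_genes = 10)
  expect_identical(c1, c2)
  i1 <- simulate_ihc(c(a = 1, b = 10), seed = 6)
  i2 <- simulate_ihc(c(a = 1, b = 10), seed = 6)
  expect_identical(i1, i2)
  g1 <- simulate_growth_curves(c(vehicle = 0.1), seed = 12)
  g2 <- simulate_growth_curves(c(vehicle = 0.1), seed = 12)
  expect_identical(g1, g2)
  # a different seed changes the draw
  expect_false(identical(a$outcomes,
                         simulate_bulk_cohort(cohort_spec(
                           n_background_genes = 20), seed = 10)$outcomes))
  # generators do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_bulk_cohort(cohort_spec(
    n_background_genes = 5), seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a null signature effect leaves stratification at background rates", {
  spec <- cohort_spec(signature_effect = 0, n_background_genes = 30)
  hits <- vapply(1:50, function(i) {
    sc <- simulate_bulk_cohort(spec, seed = 1000 + i)
    st <- stratify_hnf(score_signatures(sc$matrix, hnf_signature()))
    sum(st$stratum == "High" & sc$truth[st$sample])
  }, numeric(1))
  # with no planted shift the latent class carries no score signal:
  # a sum of 11 independent z's exceeds 12 only ~ a few % of the time
  expect_lt(mean(hits), 1)
})

test_that("the default cohort recovers latent-high samples by stratification", {
  sens <- vapply(1:40, function(i) {
    sc <- simulate_bulk_cohort(cohort_spec(), seed = 2000 + i)
    st <- stratify_hnf(score_signatures(sc$matrix, hnf_signature()))
    sum(st$stratum == "High" & sc$truth[st$sample]) / sum(sc$truth)
  }, numeric(1))
  expect_gte(mean(sens), 0.8)
})

test_that("single-cell generator plants the HNF-specific treatment effect", {
  cm <- simulate_single_cell(n_cells_per_condition = 250,
                             treatment_hnf_downscale = 2, seed = 77,
                             n_background_genes = 40)
  pb <- pseudobulk(cm)
  hnf <- hnf_signature()$genes
  ar <- setdiff(ar_signature()$genes, hnf)
  # HNF genes roughly halved in treated pseudobulk, AR genes not
  hnf_ratio <- sum(pb[hnf, "treated"]) / sum(pb[hnf, "vehicle"])
  ar_ratio <- sum(pb[ar, "treated"]) / sum(pb[ar, "vehicle"])
  expect_lt(hnf_ratio, 0.65)
  expect_gt(ar_ratio, 0.85)
  expect_error(simulate_single_cell(10, 0, seed = 1), "downscale")
})

test_that("growth generator starts at 100 mm3 with exact closed-form noise-free curves", {
  rec <- simulate_growth_curves(c(vehicle = log(2) / 7), seed = 3,
                                n_animals = 2, noise_sd = 0)
  fc <- growth_fold_change(rec)
  expect_equal(fc$volume_mm3[fc$day == 0], c(100, 100))
  expect_equal(fc$fold_change[fc$day == 28], c(16, 16))
  flat <- simulate_growth_curves(c(vehicle = 0), seed = 3, noise_sd = 0)
  expect_true(all(growth_fold_change(flat)$fold_change == 1))
  expect_error(simulate_growth_curves(c(0.1, 0.2), seed = 1), "named")
})

test_that("ihc generator output passes the stain-table invariants", {
  sim <- simulate_ihc(c(p1 = 0, p2 = 14), seed = 5, n_regions = 3,
                      cells_per_region = 200)
  expect_equal(nrow(sim$stain_counts), 6)
  totals <- rowSums(sim$stain_counts[, c("n_negative", "n_weak",
                                         "n_moderate", "n_strong")])
  expect_true(all(totals == 200))
  expect_true(all(sim$positives$n_positive <= sim$positives$n_total))
  expect_error(simulate_ihc(1:3, link_slope = NA, seed = 1))
})
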