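# Small in-code fixtures shared across test files.

# genes x samples matrix on the log2tpm scale, deterministic values
toy_expression <- function(genes = c("HNF1A", "MUC13", "OTHER"),
                           n_samples = 4, seed = 42, scale = "log2tpm") {
  withr::with_seed(seed, {
    v <- matrix(round(runif(length(genes) * n_samples, 0, 10), 3),
                nrow = length(genes),
                dimnames = list(genes, paste0("s", seq_len(n_samples))))
    expression_matrix(v, scale = scale)
  })
}

# a tiny deterministic cells x genes count matrix with two conditions
toy_cells <- function(n_per_cond = 5, genes = c("HNF1A", "MUC13", "KLK3",
                                                "BG1", "BG2"),
                      seed = 7) {
  withr::with_seed(seed, {
    n <- 2 * n_per_cond
    counts <- matrix(rpois(n * length(genes), lambda = 5), nrow = n,
                     dimnames = list(paste0("c", seq_len(n)), genes))
    counts[1, ] <- counts[1, ] + 1  # guard against a zero-total cell
    cell_matrix(counts,
                data.frame(cell = paste0("c", seq_len(n)),
                           condition = rep(c("vehicle", "treated"),
                                           each = n_per_cond)))
  })
}

expect_file_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.info(a)$size),
                   readBin(b, "raw", file.info(b)$size))
}
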