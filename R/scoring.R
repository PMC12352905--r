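#' Construct an expression matrix
#'
#' Genes-by-samples numeric matrix with unique gene symbols as rownames and
#' unique sample IDs as colnames, tagged with its scale: `"tpm"` (linear TPM)
#' or `"log2tpm"` (log2(TPM + pseudocount)).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @param scale One of `"tpm"`, `"log2tpm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("log2tpm", "tpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("`values` must have gene rownames and sample colnames")
  }
  genes <- trimws(genes)
  dup <- genes[duplicated(toupper(genes))]
  if (length(dup) > 0L) {
    stop("duplicate gene symbol(s) in matrix: ",
         paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (scale == "tpm" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative TPM value at gene '", genes[bad[["row"]]],
         "', sample '", samples[bad[["col"]]], "'")
  }
  rownames(values) <- genes
  structure(list(genes = genes, samples = samples, values = values,
                 scale_tag = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", length(x$genes), " genes x ",
      length(x$samples), " samples [", x$scale_tag, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' Log2-transform a TPM matrix
#'
#' Applies `log2(v + pseudocount)` elementwise, the transform under which
#' per-gene z-scores and summed signature scores are defined.
#'
#' @param x An [expression_matrix] on the `"tpm"` scale.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return An [expression_matrix] on the `"log2tpm"` scale.
#' @examples
#' m <- expression_matrix(matrix(c(1, 0, 3, 7), 2, 2,
#'        dimnames = list(c("g1", "g2"), c("s1", "s2"))), scale = "tpm")
#' as.matrix(log2_transform(m))
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale_tag != "tpm") {
    stop("matrix is already on the '", x$scale_tag, "' scale")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number")
  }
  expression_matrix(log2(x$values + pseudocount), scale = "log2tpm")
}

#' Per-gene z-scores across samples
#'
#' For each gene, `z = (x - mean) / sd` across the samples of the matrix
#' (sample sd, denominator n-1). The reference population is the matrix
#' itself: scores are cohort-relative. Genes with zero variance are mapped to
#' an all-zero row with a warning rather than propagating NaN.
#'
#' @param x An [expression_matrix] on the `"log2tpm"` scale.
#' @return Numeric genes-by-samples matrix of z-scores.
#' @export
gene_zscores <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale_tag != "log2tpm") {
    stop("z-scores are defined on log2-transformed values; ",
         "call log2_transform() first")
  }
  v <- x$values
  if (ncol(v) < 2L) stop("z-scores need at least 2 samples")
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sum(const), " constant gene(s) set to z = 0: ",
            paste(utils::head(x$genes[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    sdv[const] <- 1
  }
  z <- (v - mu) / sdv
  z[const, ] <- 0
  z
}

#' Summed z-score per sample for a gene signature
#'
#' The signature score of a sample is the sum, over the signature genes
#' present in the matrix, of that sample's per-gene z-scores. Gene symbols
#' are matched case-insensitively after trimming.
#'
#' @param zmatrix Genes-by-samples z-score matrix from [gene_zscores()].
#' @param signature A [gene_signature].
#' @param missing_policy What to do when signature genes are absent from the
#'   matrix: `"drop_warn"` (default) scores over the genes present and warns;
#'   `"error"` rejects, listing the missing genes.
#' @return A `score_table` data frame with columns `sample`, `signature`,
#'   `score`, `n_genes_used`, `missing_genes` (comma-separated, `""` if none).
#' @examples
#' m <- expression_matrix(matrix(c(1, 2, 3, 6, 5, 4), 3, 2,
#'        dimnames = list(c("HNF1A", "MUC13", "OTHER"), c("s1", "s2"))))
#' z <- gene_zscores(m)
#' sum_z_score(z, gene_signature("toy", c("HNF1A", "MUC13")))
#' @export
sum_z_score <- function(zmatrix, signature,
                        missing_policy = c("drop_warn", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(zmatrix), is.numeric(zmatrix),
            inherits(signature, "gene_signature"))
  idx <- match(toupper(signature$genes), toupper(trimws(rownames(zmatrix))))
  missing <- signature$genes[is.na(idx)]
  if (length(missing) == length(signature$genes)) {
    stop("no gene of signature '", signature$name, "' present in matrix")
  }
  if (length(missing) > 0L) {
    if (missing_policy == "error") {
      stop("signature '", signature$name, "' gene(s) absent from matrix: ",
           paste(missing, collapse = ", "))
    }
    warning("signature '", signature$name, "': ", length(missing),
            " gene(s) absent, scoring over ", sum(!is.na(idx)),
            " present gene(s): missing ", paste(missing, collapse = ", "))
  }
  idx <- idx[!is.na(idx)]
  scores <- colSums(zmatrix[idx, , drop = FALSE])
  out <- data.frame(
    sample = colnames(zmatrix),
    signature = signature$name,
    score = unname(scores),
    n_genes_used = length(idx),
    missing_genes = paste(missing, collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  out
}

#' Stratify samples by HNF score
#'
#' Fixed-threshold stratification of summed z-scores: `score >= high` is
#' `High`, `score <= low` is `Low`, anything in between `Intermediate`.
#' `mode = "two"` gives the binary High-vs-rest split (rest labelled `Low`)
#' used for small response cohorts.
#'
#' @param scores A `score_table` from [sum_z_score()].
#' @param high_threshold Scores at or above this are `High` (default 12).
#' @param low_threshold Scores at or below this are `Low` (default 0);
#'   must be strictly less than `high_threshold`.
#' @param mode `"three"` (High/Intermediate/Low, default) or `"two"`
#'   (High vs rest).
#' @return The input with a `stratum` factor column added.
#' @examples
#' st <- data.frame(sample = c("a", "b", "c"), signature = "HNF",
#'                  score = c(13, 5, -1), n_genes_used = 11,
#'                  missing_genes = "")
#' stratify_hnf(st)$stratum
#' @export
stratify_hnf <- function(scores, high_threshold = 12, low_threshold = 0,
                         mode = c("three", "two")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  if (!is.numeric(scores$score) || anyNA(scores$score)) {
    stop("`scores$score` must be numeric with no missing values")
  }
  if (!(is.numeric(high_threshold) && is.numeric(low_threshold) &&
        low_threshold < high_threshold)) {
    stop("thresholds must satisfy low_threshold < high_threshold")
  }
  s <- scores$score
  if (mode == "three") {
    stratum <- ifelse(s >= high_threshold, "High",
                      ifelse(s <= low_threshold, "Low", "Intermediate"))
    levels <- c("High", "Intermediate", "Low")
  } else {
    stratum <- ifelse(s >= high_threshold, "High", "Low")
    levels <- c("High", "Low")
  }
  scores$stratum <- factor(stratum, levels = levels)
  scores
}

#' Score an expression matrix with one or more signatures
#'
#' Convenience wrapper: log2-transforms if needed, computes z-scores once and
#' a summed score per signature, returning one stacked `score_table`.
#'
#' @param x An [expression_matrix] (either scale).
#' @param signatures A [gene_signature] or list of them.
#' @inheritParams log2_transform
#' @inheritParams sum_z_score
#' @return A `score_table` data frame (one row per sample x signature).
#' @export
score_signatures <- function(x, signatures, pseudocount = 1,
                             missing_policy = c("drop_warn", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(x, "expression_matrix"))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  if (x$scale_tag == "tpm") x <- log2_transform(x, pseudocount)
  z <- gene_zscores(x)
  out <- do.call(rbind, lapply(signatures, function(s) {
    sum_z_score(z, s, missing_policy)
  }))
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}
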