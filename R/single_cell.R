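#' Construct a single-cell count matrix
#'
#' Cells-by-genes matrix of non-negative integer counts with per-cell
#' metadata (treatment condition, optional cluster label).
#'
#' @param counts Integer matrix, cells in rows (rownames = cell barcodes),
#'   genes in columns (colnames = symbols).
#' @param meta Data frame with columns `cell`, `condition` and optionally
#'   `cluster`; every cell of `counts` must appear exactly once.
#' @return An object of class `cell_matrix`: list with `counts`, `meta`.
#' @export
cell_matrix <- function(counts, meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (cells x genes)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs cell rownames and gene colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell IDs")
  if (anyDuplicated(toupper(colnames(counts)))) stop("duplicate gene symbols")
  if (!is.data.frame(meta) || !all(c("cell", "condition") %in% names(meta))) {
    stop("`meta` needs columns `cell` and `condition`")
  }
  idx <- match(rownames(counts), meta$cell)
  if (anyNA(idx)) {
    stop("cells without metadata: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5L), collapse = ", "))
  }
  meta <- meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; conditions: ",
      paste(names(table(x$meta$condition)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Depth-normalize single-cell counts
#'
#' Counts-per-`scale` followed by a natural-log transform:
#' `log(1 + scale * count / total_counts_of_cell)`. The result is invariant
#' to each cell's sequencing depth.
#'
#' @param x A [cell_matrix].
#' @param scale Library-size target (default 1e4, i.e. counts per 10k).
#' @return Numeric cells-by-genes matrix of normalized expression.
#' @export
normalize_cells <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "cell_matrix"), is.numeric(scale), scale > 0)
  totals <- rowSums(x$counts)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(rownames(x$counts)[totals == 0], 5L),
               collapse = ", "))
  }
  log1p(scale * x$counts / totals)
}

#' Per-cell signature scores
#'
#' Genes are z-scored across all cells pooled over conditions (sample sd,
#' denominator n-1; constant genes give z = 0), then each cell's score is the
#' sum of its z-scores over the signature genes present in the matrix.
#' Pooling before z-scoring is what makes between-condition shifts
#' measurable.
#'
#' @param x A [cell_matrix].
#' @param signature A [gene_signature] or list of them.
#' @param scale Passed to [normalize_cells()].
#' @return A `cell_score_table` data frame: `cell`, `signature`, `score`,
#'   `condition` (and `cluster` if present in the metadata).
#' @export
cell_signature_score <- function(x, signature, scale = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  if (inherits(signature, "gene_signature")) signature <- list(signature)
  norm <- normalize_cells(x, scale)
  if (nrow(norm) < 2L) stop("need at least 2 cells to z-score")
  mu <- colMeans(norm)
  sdv <- apply(norm, 2L, stats::sd)
  sdv[sdv == 0] <- Inf  # constant genes contribute z = 0
  z <- sweep(sweep(norm, 2L, mu), 2L, sdv, "/")
  out <- do.call(rbind, lapply(signature, function(s) {
    idx <- match(toupper(s$genes), toupper(trimws(colnames(z))))
    present <- which(!is.na(idx))
    if (length(present) == 0L) {
      stop("no gene of signature '", s$name, "' present in matrix")
    }
    if (length(present) < length(s$genes)) {
      warning("signature '", s$name, "': ",
              length(s$genes) - length(present), " gene(s) absent")
    }
    data.frame(cell = rownames(z), signature = s$name,
               score = unname(rowSums(z[, idx[present], drop = FALSE])),
               condition = x$meta$condition,
               stringsAsFactors = FALSE)
  }))
  if ("cluster" %in% names(x$meta)) {
    out$cluster <- rep(x$meta$cluster, length(signature))
  }
  rownames(out) <- NULL
  class(out) <- c("cell_score_table", "data.frame")
  out
}

#' Pseudobulk aggregation by condition
#'
#' Sums raw counts over all cells of each condition, yielding a
#' genes-by-conditions matrix. Total counts are conserved exactly.
#'
#' @param x A [cell_matrix].
#' @param conditions Optional subset/order of condition labels; unknown
#'   labels are an error. Default: all conditions present, sorted.
#' @return Numeric genes-by-conditions matrix of summed counts.
#' @export
pseudobulk <- function(x, conditions = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  present <- sort(unique(x$meta$condition))
  if (is.null(conditions)) {
    conditions <- present
  } else if (!all(conditions %in% present)) {
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, present), collapse = ", "))
  }
  out <- vapply(conditions, function(cond) {
    colSums(x$counts[x$meta$condition == cond, , drop = FALSE])
  }, numeric(ncol(x$counts)))
  out <- matrix(out, ncol = length(conditions),
                dimnames = list(colnames(x$counts), conditions))
  out
}

#' Compare per-cell signature scores between two conditions
#'
#' Welch two-sample t test on the per-cell scores of one signature. The
#' reported shift is `mean(condB) - mean(condA)`, so with A = vehicle and
#' B = treated a negative shift means the treatment lowers the score.
#'
#' @param scores A `cell_score_table` from [cell_signature_score()].
#' @param signature Signature name to compare.
#' @param condA,condB Condition labels (each needs >= 2 cells).
#' @return A list with `mean_diff` (B - A), `statistic`, `df`, `p.value`,
#'   `n` (per-condition cell counts).
#' @export
compare_condition_scores <- function(scores, signature, condA, condB) {
  stopifnot(is.data.frame(scores),
            all(c("signature", "score", "condition") %in% names(scores)))
  sa <- scores$score[scores$signature == signature & scores$condition == condA]
  sb <- scores$score[scores$signature == signature & scores$condition == condB]
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("each condition needs at least 2 cells (",
         condA, ": ", length(sa), ", ", condB, ": ", length(sb), ")")
  }
  tt <- stats::t.test(sb, sa, var.equal = FALSE)
  list(mean_diff = mean(sb) - mean(sa),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, n = c(length(sa), length(sb)))
}
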