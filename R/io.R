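#' Read an expression matrix from a delimited file
#'
#' The delimiter is sniffed from the extension (`.csv` comma, otherwise
#' tab). By default the first column holds gene symbols and the header row
#' sample IDs; `orientation = "samples_by_genes"` reads the transpose.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`.
#' @param scale Scale tag of the stored values (`"tpm"` or `"log2tpm"`).
#' @return An [expression_matrix].
#' @export
read_expression <- function(path,
                            orientation = c("genes_by_samples",
                                            "samples_by_genes"),
                            scale = c("tpm", "log2tpm")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  df <- read_delimited(path)
  if (ncol(df) < 2L) stop("'", path, "' has no sample columns")
  labels <- trimws(as.character(df[[1L]]))
  numeric_part <- df[, -1L, drop = FALSE]
  for (j in seq_along(numeric_part)) {
    col <- numeric_part[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop("non-numeric value in '", path, "', column '",
           names(numeric_part)[j], "', row ", bad)
    }
  }
  m <- as.matrix(numeric_part)
  rownames(m) <- labels
  if (orientation == "samples_by_genes") m <- t(m)
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' @param x An [expression_matrix].
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delimited(df, path)
}

#' Read sample metadata (response and survival columns)
#'
#' Expected columns: `sample` plus any of `response`
#' (`responder`/`nonresponder`), `tot_time`, `tot_event`, `os_time`,
#' `os_event`, `group`.
#'
#' @param path CSV/TSV path.
#' @return Validated data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delimited(path)
  if (!"sample" %in% names(df)) stop("metadata needs a `sample` column")
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in metadata")
  if ("response" %in% names(df)) {
    bad <- setdiff(unique(df$response), c("responder", "nonresponder", NA))
    if (length(bad) > 0L) {
      stop("invalid response value(s): ", paste(bad, collapse = ", "))
    }
  }
  for (col in intersect(c("tot_time", "os_time"), names(df))) {
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative times in ", col)
  }
  for (col in intersect(c("tot_event", "os_event"), names(df))) {
    if (!all(df[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  }
  df
}

#' Read a growth-measurement table
#'
#' Expected columns: `animal`, `arm`, `day`, `volume_mm3`.
#'
#' @param path CSV/TSV path.
#' @return Validated growth-record data frame.
#' @export
read_growth_table <- function(path) {
  validate_growth_records(read_delimited(path))
}

#' Read a stain-intensity count table
#'
#' Expected columns: `region`, `sample`, `n_negative`, `n_weak`,
#' `n_moderate`, `n_strong`.
#'
#' @param path CSV/TSV path.
#' @return Validated data frame.
#' @export
read_stain_counts <- function(path) {
  df <- read_delimited(path)
  need <- c("region", "sample", "n_negative", "n_weak", "n_moderate",
            "n_strong")
  if (!all(need %in% names(df))) {
    stop("stain-count table needs columns: ", paste(need, collapse = ", "))
  }
  cnt <- as.matrix(df[, need[-(1:2)]])
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("stain counts must be non-negative integers")
  }
  if (any(rowSums(cnt) == 0)) stop("region(s) with zero total cells")
  df
}

#' Read a single-cell matrix from MTX triplet or dense TSV
#'
#' For `format = "mtx"`, `path` is the MatrixMarket file and `genes_path` /
#' `barcodes_path` are one-symbol-per-line text files (genes in MTX rows,
#' cells in columns, the usual triplet layout). For `format = "dense"`,
#' `path` is a TSV/CSV with cells in rows (first column = barcode) and genes
#' in the header.
#'
#' @param path Matrix path.
#' @param meta_path Cell-metadata CSV/TSV (`cell`, `condition`, optional
#'   `cluster`).
#' @param format `"mtx"` or `"dense"`.
#' @param genes_path,barcodes_path Required for `format = "mtx"`.
#' @return A [cell_matrix].
#' @export
read_cell_matrix <- function(path, meta_path, format = c("mtx", "dense"),
                             genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  meta <- read_delimited(meta_path)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(barcodes_path)) {
      stop("MTX input needs `genes_path` and `barcodes_path`")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- trimws(readLines(genes_path, warn = FALSE))
    barcodes <- trimws(readLines(barcodes_path, warn = FALSE))
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      stop("MTX dimensions do not match gene/barcode files")
    }
    counts <- t(m)
    dimnames(counts) <- list(barcodes, genes)
  } else {
    df <- read_delimited(path)
    counts <- as.matrix(df[, -1L, drop = FALSE])
    rownames(counts) <- as.character(df[[1L]])
  }
  cell_matrix(counts, meta)
}

#' Write a score table (or any data frame) as TSV
#'
#' @param x Data frame.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  write_delimited(as.data.frame(x), path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(first)]
  nfield <- lengths(strsplit(first, sep, fixed = TRUE))
  if (length(unique(nfield)) > 1L) {
    stop("ragged rows in '", path, "': row ",
         which(nfield != nfield[1L])[1L], " has ",
         nfield[which(nfield != nfield[1L])[1L]], " fields, expected ",
         nfield[1L])
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

write_delimited <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
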