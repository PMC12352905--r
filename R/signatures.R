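#' Construct a gene signature
#'
#' A gene signature is a named, ordered list of unique gene symbols. Symbols
#' are trimmed of surrounding whitespace; duplicates (case-insensitive) are
#' collapsed to the first occurrence.
#'
#' @param name Signature name (single non-empty string).
#' @param genes Character vector of gene symbols.
#' @return An object of class `gene_signature`: a list with elements `name`
#'   and `genes`.
#' @examples
#' gene_signature("toy", c("HNF1A", "MUC13"))
#' @export
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(genes)) stop("`genes` must be a character vector")
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("signature '", name, "' has no genes")
  genes <- genes[!duplicated(toupper(genes))]
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, " (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' The 11-gene HNF signature
#'
#' The gastrointestinal-lineage panel consists of the master transcription
#' factors HNF1A and HNF4G together with nine strong, direct downstream
#' targets (AKR1C3, ANG, APOH, CLRN3, GAS2, METTL7B, MUC13, SGK2, UGT2B15).
#' The summed z-score of these 11 genes over a cohort is the HNF score used
#' to call GI-transcriptome-positive tumors.
#'
#' @return A [gene_signature] of length 11 named `"HNF"`.
#' @examples
#' length(hnf_signature())  # 11
#' @export
hnf_signature <- function() {
  gene_signature("HNF", c(
    "HNF1A", "HNF4G",
    "AKR1C3", "ANG", "APOH", "CLRN3", "GAS2",
    "METTL7B", "MUC13", "SGK2", "UGT2B15"
  ))
}

#' Default androgen-receptor target panels
#'
#' The AR score is the summed z-score over the union of two published AR
#' target-gene signatures. The exact member lists live in external
#' publications, so the panels shipped here are widely used
#' androgen-response gene lists provided as editable defaults: replace them
#' with your preferred lists via [read_gmt()] if needed.
#'
#' `ar10_signature()` is a 10-gene AR-activity panel; `hieronymus_signature()`
#' is a Hieronymus-style androgen-response panel; `ar_signature()` is their
#' de-duplicated union (the combined panel the AR score uses).
#'
#' @return A [gene_signature].
#' @examples
#' length(ar_signature())
#' @export
ar10_signature <- function() {
  gene_signature("AR_10_gene", c(
    "KLK3", "KLK2", "FKBP5", "STEAP1", "STEAP2",
    "PLPP1", "RAB3B", "NDRG1", "ALDH1A3", "PMEPA1"
  ))
}

#' @rdname ar10_signature
#' @export
hieronymus_signature <- function() {
  gene_signature("AR_Hieronymus", c(
    "KLK3", "KLK2", "TMPRSS2", "FKBP5", "NKX3-1", "PMEPA1", "ABCC4",
    "ACSL3", "ZBTB10", "HERC3", "PTGER4", "EAF2", "MED28", "NNMT",
    "MAF", "GNMT", "CENPN", "ELL2", "ADAM7", "C1orf116"
  ))
}

#' @rdname ar10_signature
#' @export
ar_signature <- function() {
  combine_signatures(ar10_signature(), hieronymus_signature(), name = "AR")
}

#' Combine two gene signatures
#'
#' De-duplicated union preserving first-seen order: genes of `a` followed by
#' genes of `b` not already present (case-insensitive matching).
#'
#' @param a,b [gene_signature] objects.
#' @param name Name of the combined signature.
#' @return A [gene_signature].
#' @examples
#' combine_signatures(gene_signature("x", c("A", "B")),
#'                    gene_signature("y", c("B", "C")), "xy")
#' @export
combine_signatures <- function(a, b, name) {
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  gene_signature(name, c(a$genes, b$genes))
}

#' Read gene signatures from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty gene
#' fields are skipped; duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty")
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in '", path,
           "': expected at least 3 tab-separated fields")
    }
    sigs[[i]] <- gene_signature(fields[[1]], fields[-(1:2)])
  }
  names(sigs) <- vapply(sigs, function(s) s$name, character(1))
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A [gene_signature] or list of them.
#' @param path Output path.
#' @param description Description field (second GMT column), recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = "na") {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  description <- rep_len(description, length(signatures))
  lines <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    paste(c(s$name, description[[i]], s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
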