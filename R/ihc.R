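#' IHC H-score from nuclear stain-intensity counts
#'
#' Cell counts at the four intensity levels are converted to percentages of
#' the region total, then weighted 1x (weak), 2x (moderate), 3x (strong):
#' `H = 100 * (n_weak + 2 n_moderate + 3 n_strong) / total`, bounded in
#' \[0, 300\]. Vectorized over regions.
#'
#' @param n_negative,n_weak,n_moderate,n_strong Non-negative cell counts per
#'   intensity level; each region's total must be positive.
#' @return H-score(s) in \[0, 300\].
#' @examples
#' h_score(0, 50, 50, 0)  # 150
#' @export
h_score <- function(n_negative, n_weak, n_moderate, n_strong) {
  counts <- cbind(n_negative, n_weak, n_moderate, n_strong)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("stain counts must be finite and non-negative")
  }
  total <- rowSums(counts)
  if (any(total == 0)) stop("region(s) with zero total cells")
  unname(100 * (counts[, 2L] + 2 * counts[, 3L] + 3 * counts[, 4L]) / total)
}

#' Mean H-score per sample across regions
#'
#' Unweighted mean of region-level H-scores per sample, with SEM (sd with
#' denominator n-1 over sqrt(n); `NA` for a single region).
#'
#' @param regions Data frame with columns `region`, `sample`, `n_negative`,
#'   `n_weak`, `n_moderate`, `n_strong` (see [read_stain_counts()]).
#' @param sample Optional sample ID(s) to restrict to.
#' @return Data frame with columns `sample`, `n_regions`, `mean_h`, `sem`.
#' @export
mean_h_score <- function(regions, sample = NULL) {
  need <- c("region", "sample", "n_negative", "n_weak", "n_moderate",
            "n_strong")
  if (!is.data.frame(regions) || !all(need %in% names(regions))) {
    stop("stain-count table needs columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(sample)) {
    regions <- regions[regions$sample %in% sample, , drop = FALSE]
    if (nrow(regions) == 0L) {
      stop("no regions for sample(s): ", paste(sample, collapse = ", "))
    }
  }
  h <- h_score(regions$n_negative, regions$n_weak, regions$n_moderate,
               regions$n_strong)
  out <- do.call(rbind, lapply(split(h, regions$sample), function(hs) {
    data.frame(n_regions = length(hs), mean_h = mean(hs),
               sem = if (length(hs) >= 2L) {
                 stats::sd(hs) / sqrt(length(hs))
               } else NA_real_)
  }))
  out <- data.frame(sample = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Positive-cell fraction
#'
#' Fraction of positively stained cells among the total counted (marker
#' scoring, e.g. Ki67 or p21, where a fixed total of cells — typically
#' 5,000 per condition — is tallied rather than an H-score).
#'
#' @param n_positive,n_total Non-negative counts, `n_positive <= n_total`,
#'   `n_total > 0`. Vectorized.
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' positive_fraction(1250, 5000)  # 0.25
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (any(!is.finite(n_positive)) || any(!is.finite(n_total)) ||
      any(n_positive < 0) || any(n_total <= 0)) {
    stop("counts must be finite, n_positive >= 0 and n_total > 0")
  }
  if (any(n_positive > n_total)) {
    stop("n_positive cannot exceed n_total")
  }
  n_positive / n_total
}
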