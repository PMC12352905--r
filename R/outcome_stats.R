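#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with both margins fixed. With the observed count
#' `a` in cell (1,1), the reference distribution of the (1,1) count k is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (summation convention),
#' with a small relative tolerance guarding against floating-point ties:
#' `p = sum P(k) over { k : P(k) <= P(a) * (1 + 1e-7) }`.
#'
#' Rows are conventionally strata (High/Low), columns outcome
#' (nonresponder/responder). If any row or column margin is zero the table
#' carries no information and p = 1 is returned with a warning.
#'
#' @param a,b,c,d Non-negative integer counts: `a`,`b` first row,
#'   `c`,`d` second row. Alternatively pass a 2x2 matrix as `a`.
#' @return A list of class `fisher_exact` with elements `p.value`, `table`,
#'   `method`.
#' @examples
#' fisher_exact_2x2(4, 1, 3, 17)$p.value  # 0.0123
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2L, 2L)
  }
  counts <- as.vector(tab)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("all four counts must be non-negative integers")
  }
  tab <- matrix(as.numeric(round(counts)), 2L, 2L, dimnames = dimnames(tab))
  n <- sum(tab)
  if (n < 1) stop("table total must be at least 1")
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L])
  out <- list(table = tab,
              method = "two-sided Fisher's exact test (summation convention)")
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("a table margin is zero; the exact test is degenerate (p = 1)")
    out$p.value <- 1
  } else {
    klo <- max(0, r1 + c1 - n)
    khi <- min(r1, c1)
    k <- klo:khi
    pk <- stats::dhyper(k, c1, n - c1, r1)
    p_obs <- pk[k == tab[1L, 1L]]
    out$p.value <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  }
  class(out) <- "fisher_exact"
  out
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("<fisher_exact> p =", format(x$p.value, digits = 4), "\n")
  print(x$table)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. For
#' perfectly collinear data (|r| = 1) the p-value is 0.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A list with `estimate` (r), `statistic` (t), `df`, `p.value`, `n`.
#' @examples
#' pearson_correlation(1:5, c(2, 4, 5, 4, 8))
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  list(estimate = r, statistic = tstat, df = df, p.value = p, n = n)
}

#' Tumor volume from caliper measurements
#'
#' `V = (D * d * h) / 6` in mm^3, with `D` the long diameter, `d` the short
#' diameter and `h` the height, all in mm. Vectorized.
#'
#' @param D,d,h Positive lengths in mm, `D >= d`.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 8, 6)  # 80
#' @export
tumor_volume <- function(D, d, h) {
  stopifnot(is.numeric(D), is.numeric(d), is.numeric(h))
  if (any(D <= 0 | d <= 0 | h <= 0)) {
    stop("all dimensions must be positive")
  }
  if (any(D < d)) stop("long diameter D must be >= short diameter d")
  (D * d * h) / 6
}

#' Per-animal tumor-growth fold change versus day 0
#'
#' For each animal, volume at each day divided by that animal's day-0
#' (treatment start) volume.
#'
#' @param records Data frame with columns `animal`, `arm`, `day`,
#'   `volume_mm3` (see [read_growth_table()]); per animal, days must be
#'   strictly increasing and include day 0.
#' @return The records with a `fold_change` column added.
#' @export
growth_fold_change <- function(records) {
  records <- validate_growth_records(records)
  split_idx <- split(seq_len(nrow(records)), records$animal)
  fc <- numeric(nrow(records))
  for (idx in split_idx) {
    day0 <- idx[records$day[idx] == 0]
    if (length(day0) != 1L) {
      stop("animal '", records$animal[idx[1L]],
           "' lacks a single day-0 measurement")
    }
    fc[idx] <- records$volume_mm3[idx] / records$volume_mm3[day0]
  }
  records$fold_change <- fc
  records
}

#' Arm-level mean fold change with SEM
#'
#' Aggregates [growth_fold_change()] output per arm and day: unweighted mean
#' across animals and SEM (sd with denominator n-1 over sqrt(n); `NA` when a
#' single animal).
#'
#' @inheritParams growth_fold_change
#' @return Data frame with columns `arm`, `day`, `n`, `mean_fold_change`,
#'   `sem`.
#' @export
summarize_growth <- function(records) {
  fc <- growth_fold_change(records)
  key <- interaction(fc$arm, fc$day, drop = TRUE)
  out <- do.call(rbind, lapply(split(fc, key), function(g) {
    data.frame(arm = g$arm[1L], day = g$day[1L], n = nrow(g),
               mean_fold_change = mean(g$fold_change),
               sem = if (nrow(g) >= 2L) {
                 stats::sd(g$fold_change) / sqrt(nrow(g))
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$arm, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treated-versus-vehicle volume ratio at a given day
#'
#' Mean fold change (each animal versus its own day 0) of the treated arm
#' divided by the mean fold change of the vehicle arm at the stated day. A
#' ratio below 1 indicates growth inhibition relative to vehicle.
#'
#' @param records Growth records covering both arms (columns `animal`,
#'   `arm`, `day`, `volume_mm3`).
#' @param treated_arm,vehicle_arm Arm labels to compare.
#' @param day Day at which to compare (must be measured in both arms).
#' @return A list with `ratio`, `day`, `n_treated`, `n_vehicle`.
#' @export
arm_volume_ratio <- function(records, treated_arm, vehicle_arm = "vehicle",
                             day) {
  fc <- growth_fold_change(records)
  pick <- function(arm) {
    sel <- fc$arm == arm & fc$day == day
    if (!any(sel)) {
      stop("arm '", arm, "' has no measurement at day ", day)
    }
    fc$fold_change[sel]
  }
  tr <- pick(treated_arm)
  ve <- pick(vehicle_arm)
  list(ratio = mean(tr) / mean(ve), day = day,
       n_treated = length(tr), n_vehicle = length(ve))
}

validate_growth_records <- function(records) {
  need <- c("animal", "arm", "day", "volume_mm3")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("growth records need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("growth records are empty")
  if (any(!is.finite(records$volume_mm3)) || any(records$volume_mm3 <= 0)) {
    stop("volumes must be positive and finite")
  }
  for (g in split(records$day, records$animal)) {
    if (any(diff(sort(g)) == 0)) stop("duplicate day for an animal")
  }
  records <- records[order(records$animal, records$day), , drop = FALSE]
  rownames(records) <- NULL
  records
}
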