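#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' is the number of events and `n_i` the number at risk at `t_i`. Subjects
#' censored exactly at an event time are counted at risk for that time
#' (standard convention).
#'
#' @param time Non-negative follow-up times (months).
#' @param event Event indicator: 1 observed, 0 censored.
#' @return An object of class `km_curve`: a data-frame-backed list with
#'   columns `time` (distinct event times, ascending), `n_risk`, `n_event`,
#'   `surv`, plus attributes `n` (subjects) and `n_events`.
#' @examples
#' km_estimator(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' @export
km_estimator <- function(time, event) {
  stopifnot(is.numeric(time), length(time) >= 1L)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative")
  }
  event <- as.integer(event)
  if (length(event) != length(time) || !all(event %in% c(0L, 1L))) {
    stop("`event` must be a 0/1 vector matching `time`")
  }
  etimes <- sort(unique(time[event == 1L]))
  if (length(etimes) == 0L) {
    curve <- data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), surv = numeric(0))
  } else {
    n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(etimes, function(t) sum(time == t & event == 1L),
                      numeric(1))
    curve <- data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                        surv = cumprod(1 - n_event / n_risk))
  }
  structure(curve, class = c("km_curve", "data.frame"),
            n = length(time), n_events = sum(event))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", attr(x, "n"), "subjects,", attr(x, "n_events"),
      "events\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step function; `S(t) = 1` before the first event.
#'
#' @param curve A [km_estimator()] result.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- sum(curve$time <= ti)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest observed event time at which `S(t) <= 0.5`; `NA` with
#' `reached = FALSE` when the curve never drops to 0.5.
#'
#' @param curve A [km_estimator()] result.
#' @return A list with `median` (months or `NA`) and `reached` (logical).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0L) {
    list(median = NA_real_, reached = FALSE)
  } else {
    list(median = curve$time[hit[1L]], reached = TRUE)
  }
}

#' Log-rank (Mantel-Cox) test for k groups
#'
#' At each distinct event time, observed events per group are compared with
#' the expectation under the null that all groups share one hazard; the
#' covariance of the observed-minus-expected vector uses the hypergeometric
#' variance with the simultaneous-event (tie) convention. The chi-square
#' statistic has k - 1 degrees of freedom and is invariant under group
#' relabeling. If no events occur the statistic is 0 and p = 1.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param group Group labels (k >= 2 non-empty groups).
#' @return A list of class `logrank_test` with `statistic`, `df`, `p.value`,
#'   `observed`, `expected`, `n` (per-group sizes).
#' @examples
#' logrank_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 0),
#'              c("a", "a", "a", "b", "b", "b"))
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("`event` must be 0/1")
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 non-empty groups")
  n_g <- table(group)

  etimes <- sort(unique(time[event == 1L]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in etimes) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_gt <- vapply(levels(group), function(g) sum(at_risk & group == g),
                   numeric(1))
    ev <- event == 1L & time == t
    d_t <- sum(ev)
    d_gt <- vapply(levels(group), function(g) sum(ev & group == g),
                   numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      p_g <- n_gt / n_t
      tie <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + tie * (diag(p_g, k) - tcrossprod(p_g))
    }
  }
  z <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  stat <- if (length(etimes) == 0L || all(abs(z) < 1e-12) ||
              all(abs(Vsub) < 1e-12)) {
    0
  } else {
    drop(t(z) %*% solve(Vsub, z))
  }
  structure(list(statistic = stat, df = k - 1L,
                 p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                 observed = O, expected = E, n = as.vector(n_g)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("<logrank_test> chi-square =", format(x$statistic, digits = 4),
      "on", x$df, "df, p =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}
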