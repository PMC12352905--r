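#' Specification of a synthetic bulk CRPC cohort
#'
#' Parameters of the generative model behind [simulate_bulk_cohort()]: a
#' cohort with a latent HNF-high subgroup whose 11 signature genes are
#' shifted upward, whose probability of non-response to AR-pathway
#' inhibition is elevated, and whose time-on-treatment and overall-survival
#' hazards are multiplied by a common hazard ratio.
#'
#' Defaults echo the printed structure of the 25-patient response cohort:
#' 20% latent-high, non-response probabilities of 0.8 (high) versus 0.15
#' (low), and a per-gene shift of 3 within-gene standard deviations so that
#' latent-high samples sit clearly above the sum-z threshold of 12 while the
#' rest cluster near 0.
#'
#' @param n_samples Cohort size (default 25).
#' @param frac_high Fraction of latent HNF-high samples, in (0,1).
#' @param signature_effect Mean log2 shift of the 11 signature genes in
#'   latent-high samples, in units of the per-gene sd (default 3).
#' @param p_nonresponse_high,p_nonresponse_low Non-response probabilities by
#'   latent class.
#' @param hazard_ratio_high Hazard multiplier for latent-high samples
#'   (applies to both time on treatment and overall survival; default 3).
#' @param censor_rate Probability a follow-up time is censored (default 0.2).
#' @param n_background_genes Number of non-signature genes (default 200).
#' @param median_tot_low,median_os_low Median time on treatment / overall
#'   survival (months) of the latent-low class (defaults 8 and 30).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 25, frac_high = 0.2,
                        signature_effect = 3,
                        p_nonresponse_high = 0.8, p_nonresponse_low = 0.15,
                        hazard_ratio_high = 3, censor_rate = 0.2,
                        n_background_genes = 200,
                        median_tot_low = 8, median_os_low = 30) {
  spec <- list(n_samples = n_samples, frac_high = frac_high,
               signature_effect = signature_effect,
               p_nonresponse_high = p_nonresponse_high,
               p_nonresponse_low = p_nonresponse_low,
               hazard_ratio_high = hazard_ratio_high,
               censor_rate = censor_rate,
               n_background_genes = n_background_genes,
               median_tot_low = median_tot_low,
               median_os_low = median_os_low)
  with(spec, {
    stopifnot(n_samples >= 2, n_background_genes >= 0,
              frac_high > 0, frac_high < 1,
              p_nonresponse_high >= 0, p_nonresponse_high <= 1,
              p_nonresponse_low >= 0, p_nonresponse_low <= 1,
              censor_rate >= 0, censor_rate < 1,
              hazard_ratio_high > 0, is.finite(signature_effect),
              median_tot_low > 0, median_os_low > 0)
  })
  structure(spec, class = "cohort_spec")
}

#' Simulate a bulk expression cohort with outcomes
#'
#' Background genes and the combined AR panel get lognormal TPM noise
#' (log2-TPM ~ Normal with per-gene baseline drawn uniformly on \[2, 8\] and
#' unit sd); the 11 HNF-signature genes are additionally shifted by
#' `signature_effect` sd in latent-high samples. Response is Bernoulli per latent class; time on treatment and
#' overall survival are exponential with the latent-high hazard multiplied
#' by `hazard_ratio_high`; censored records have their time truncated
#' uniformly. Fully reproducible from `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed (required; the global RNG state is
#'   preserved).
#' @return A list of class `synthetic_cohort` with elements `matrix`
#'   (an [expression_matrix] on the TPM scale), `truth` (logical latent-high
#'   per sample) and `outcomes` (data frame: `sample`, `response`,
#'   `tot_time`, `tot_event`, `os_time`, `os_event`, `group`).
#' @examples
#' sc <- simulate_bulk_cohort(cohort_spec(), seed = 1)
#' table(sc$truth)
#' @export
simulate_bulk_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_seed(seed)
  withr::with_seed(seed, {
    n <- spec$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    n_high <- max(1L, round(spec$frac_high * n))
    truth <- stats::setNames(seq_len(n) %in% sample.int(n, n_high), samples)

    sig <- hnf_signature()$genes
    genes <- c(sig, ar_signature()$genes,
               sprintf("BG%04d", seq_len(spec$n_background_genes)))
    base <- stats::runif(length(genes), 2, 8)
    logv <- matrix(stats::rnorm(length(genes) * n, mean = base, sd = 1),
                   nrow = length(genes), ncol = n,
                   dimnames = list(genes, samples))
    logv[sig, truth] <- logv[sig, truth] + spec$signature_effect
    mat <- expression_matrix(2^logv, scale = "tpm")

    p_nr <- ifelse(truth, spec$p_nonresponse_high, spec$p_nonresponse_low)
    response <- ifelse(stats::runif(n) < p_nr, "nonresponder", "responder")

    draw_times <- function(median_low) {
      rate <- log(2) / median_low *
        ifelse(truth, spec$hazard_ratio_high, 1)
      t_full <- stats::rexp(n, rate)
      cens <- stats::runif(n) < spec$censor_rate
      list(time = ifelse(cens, t_full * stats::runif(n), t_full),
           event = as.integer(!cens))
    }
    tot <- draw_times(spec$median_tot_low)
    os <- draw_times(spec$median_os_low)
    outcomes <- data.frame(
      sample = samples, response = response,
      tot_time = tot$time, tot_event = tot$event,
      os_time = os$time, os_event = os$event,
      group = ifelse(truth, "latent_high", "latent_low"),
      stringsAsFactors = FALSE
    )
    structure(list(matrix = mat, truth = truth, outcomes = outcomes,
                   spec = spec, seed = seed),
              class = "synthetic_cohort")
  })
}

#' Simulate single-cell counts with a planted treatment effect
#'
#' Negative-binomial counts for two conditions (`vehicle`, `treated`) over
#' the 11 HNF-signature genes, the combined AR panel and background genes.
#' Gene base means are lognormal; each cell has a lognormal depth factor.
#' In treated cells the HNF-signature gene means are divided by
#' `treatment_hnf_downscale`; AR-panel means are unchanged.
#'
#' @param n_cells_per_condition Cells per condition (default 1000).
#' @param treatment_hnf_downscale Factor (> 0) dividing HNF-gene means in
#'   treated cells; 1 is the null (default 2).
#' @param seed Integer RNG seed (required).
#' @param n_background_genes Background genes (default 500). Keep this
#'   large relative to the signature panels: depth normalization couples
#'   genes compositionally, and only when the panels are a small fraction
#'   of the library (as in real transcriptome-wide data) is the knock-on
#'   effect of the planted HNF suppression on other genes' normalized
#'   values negligible.
#' @param dispersion Negative-binomial size parameter (default 10; larger is
#'   closer to Poisson).
#' @param depth_sd SD of the per-cell log-normal depth factor (default 0.3).
#' @return A [cell_matrix].
#' @export
simulate_single_cell <- function(n_cells_per_condition = 1000,
                                 treatment_hnf_downscale = 2, seed,
                                 n_background_genes = 500,
                                 dispersion = 10, depth_sd = 0.3) {
  stopifnot(n_cells_per_condition >= 2, treatment_hnf_downscale > 0,
            n_background_genes >= 0, dispersion > 0, depth_sd >= 0)
  check_seed(seed)
  withr::with_seed(seed, {
    hnf <- hnf_signature()$genes
    ar <- ar_signature()$genes
    genes <- c(hnf, ar, sprintf("BG%04d", seq_len(n_background_genes)))
    n_cond <- n_cells_per_condition
    n_cells <- 2L * n_cond
    condition <- rep(c("vehicle", "treated"), each = n_cond)
    cells <- sprintf("%s_%04d", c("v", "t")[(condition == "treated") + 1L],
                     c(seq_len(n_cond), seq_len(n_cond)))

    base_mean <- stats::rlnorm(length(genes), meanlog = log(2), sdlog = 1)
    names(base_mean) <- genes
    depth <- stats::rlnorm(n_cells, 0, depth_sd)
    mu <- outer(depth, base_mean)               # cells x genes
    mu[condition == "treated", hnf] <-
      mu[condition == "treated", hnf] / treatment_hnf_downscale
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow = n_cells,
                     dimnames = list(cells, genes))
    cell_matrix(counts, data.frame(cell = cells, condition = condition,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate IHC stain-count tables linked to an expression score
#'
#' Per sample, `n_regions` regions of `cells_per_region` nuclei are tallied
#' into the four intensity levels from a multinomial whose probabilities
#' follow a proportional-odds (cumulative-logit) model in the linked score:
#' `P(level <= j) = plogis(cutpoint_j - link_slope * (score - link_center))`.
#' A positive slope plants a monotone expression-to-intensity link
#' (`link_slope = 0` is the flat/null link). A Ki67/p21-style positive-cell
#' count per sample is drawn binomially with success probability
#' `plogis(link_slope * (score - link_center))`.
#'
#' @param scores Numeric vector of per-sample expression scores (e.g. HNF
#'   sum-z scores); names become sample IDs.
#' @param link_slope Slope of the monotone link (default 0.5; 0 = flat).
#' @param seed Integer RNG seed (required).
#' @param link_center Score at which intensity odds are balanced
#'   (default 6, midway between the Low and High thresholds of 0 and 12).
#' @param n_regions Regions per sample (default 3, as for triplicate cores).
#' @param cells_per_region Nuclei tallied per region (default 500).
#' @param n_total_positive Cells tallied for the positive-cell count
#'   (default 5000).
#' @return A list with `stain_counts` (region-level data frame:
#'   `region`, `sample`, `n_negative`, `n_weak`, `n_moderate`, `n_strong`),
#'   `positives` (data frame: `sample`, `n_positive`, `n_total`) and
#'   `scores` (the input scores, named by sample).
#' @export
simulate_ihc <- function(scores, link_slope = 0.5, seed, link_center = 6,
                         n_regions = 3, cells_per_region = 500,
                         n_total_positive = 5000) {
  stopifnot(is.numeric(scores), length(scores) >= 1,
            is.numeric(link_slope), length(link_slope) == 1L,
            is.finite(link_slope),
            n_regions >= 1, cells_per_region >= 1, n_total_positive >= 1)
  check_seed(seed)
  if (is.null(names(scores))) {
    names(scores) <- sprintf("PDX%02d", seq_along(scores))
  }
  cutpoints <- c(-2, 0, 2)
  withr::with_seed(seed, {
    rows <- vector("list", length(scores) * n_regions)
    i <- 0L
    for (s in names(scores)) {
      eta <- link_slope * (scores[[s]] - link_center)
      cum <- stats::plogis(cutpoints - eta)
      probs <- diff(c(0, cum, 1))
      for (r in seq_len(n_regions)) {
        cnt <- stats::rmultinom(1L, cells_per_region, probs)[, 1L]
        i <- i + 1L
        rows[[i]] <- data.frame(
          region = sprintf("%s_r%d", s, r), sample = s,
          n_negative = cnt[1L], n_weak = cnt[2L],
          n_moderate = cnt[3L], n_strong = cnt[4L],
          stringsAsFactors = FALSE)
      }
    }
    stain <- do.call(rbind, rows)
    rownames(stain) <- NULL
    p_pos <- stats::plogis(link_slope * (scores - link_center))
    positives <- data.frame(
      sample = names(scores),
      n_positive = stats::rbinom(length(scores), n_total_positive, p_pos),
      n_total = n_total_positive, stringsAsFactors = FALSE)
    list(stain_counts = stain, positives = positives, scores = scores)
  })
}

#' Simulate exponential tumor-growth curves per treatment arm
#'
#' Each animal starts at 100 mm^3 (treatment start) and grows as
#' `V(t) = 100 * exp(rate * t)` with multiplicative lognormal measurement
#' noise at days after day 0 (the day-0 measurement is the exact 100 mm^3
#' baseline fold changes are taken against).
#'
#' @param arms Named numeric vector of per-day exponential growth rates,
#'   e.g. `c(vehicle = log(2)/7, pelabresib = 0.02)`.
#' @param seed Integer RNG seed (required).
#' @param n_animals Animals per arm (default 5).
#' @param days Measurement days including 0 (default `seq(0, 28, by = 7)`).
#' @param noise_sd SD of the lognormal measurement noise (default 0.1).
#' @param start_volume Volume at treatment start, mm^3 (default 100).
#' @return A growth-record data frame: `animal`, `arm`, `day`, `volume_mm3`.
#' @export
simulate_growth_curves <- function(arms, seed, n_animals = 5,
                                   days = seq(0, 28, by = 7),
                                   noise_sd = 0.1, start_volume = 100) {
  if (is.null(names(arms)) || any(!nzchar(names(arms))) ||
      anyDuplicated(names(arms)) || !is.numeric(arms) ||
      any(!is.finite(arms))) {
    stop("`arms` must be a uniquely named numeric vector of finite rates")
  }
  stopifnot(n_animals >= 1, length(days) >= 1, all(days >= 0), 0 %in% days,
            noise_sd >= 0, start_volume > 0)
  check_seed(seed)
  days <- sort(unique(days))
  withr::with_seed(seed, {
    rows <- list()
    for (arm in names(arms)) {
      for (a in seq_len(n_animals)) {
        noise <- ifelse(days == 0, 0, stats::rnorm(length(days), 0, noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", arm, a), arm = arm, day = days,
          volume_mm3 = start_volume * exp(arms[[arm]] * days + noise),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

check_seed <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  invisible(as.integer(seed))
}
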