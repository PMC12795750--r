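#' Exposure-risk ratio for one racial/ethnic group
#'
#' The exposure-risk ratio (ERR) compares a group's exposure-weighted
#' population share with the same quantity for the total population:
#' `ERR_j = [sum(omega_i p_ij)/sum(p_ij)] / [sum(omega_i t_ij)/sum(t_ij)]`,
#' where `omega_i` is tract i's exposure prevalence, `p_ij` the group
#' population and `t_ij` the total population. An ERR above 1 means the
#' group is over-represented among the exposed relative to its
#' nationwide representation. Tracts with missing (excluded) prevalence
#' are dropped pairwise.
#'
#' @param omega Per-tract exposure prevalence (NA for excluded tracts).
#' @param p Per-tract population of group j.
#' @param t Per-tract total population.
#' @return The ERR, or `NA` when the denominator prevalence is zero.
#' @export
compute_err <- function(omega, p, t) {
  stopifnot(length(omega) == length(p), length(p) == length(t))
  keep <- !is.na(omega)
  omega <- omega[keep]; p <- p[keep]; t <- t[keep]
  if (sum(p) <= 0 || sum(t) <= 0)
    stop("group and total populations must have positive sums")
  num <- sum(omega * p) / sum(p)
  den <- sum(omega * t) / sum(t)
  if (den == 0) return(NA_real_)
  num / den
}

#' Cumulative exposure-risk ratio
#'
#' The ERR for cumulative noise pollution, with the per-tract prevalence
#' replaced by the product of the workplace and transportation
#' prevalences. Tracts missing either prevalence are dropped.
#'
#' @param omega_work,omega_transport Per-tract prevalences of the two
#'   sources.
#' @inheritParams compute_err
#' @export
compute_cumulative_err <- function(omega_work, omega_transport, p, t) {
  keep <- !is.na(omega_work) & !is.na(omega_transport)
  compute_err((omega_work * omega_transport)[keep], p[keep], t[keep])
}

#' Bootstrap an exposure-risk ratio
#'
#' Resamples whole tracts with replacement `n_boot` times and recomputes
#' the ERR on each replicate. The central estimate is the 50th
#' percentile of the replicate ERRs and the 95% CI the 2.5th/97.5th
#' percentiles.
#'
#' @param data A data.frame with columns `p` and `t` plus either `omega`
#'   (single-source) or `omega_work` and `omega_transport`
#'   (`source = "cumulative"`).
#' @param group Label for the racial/ethnic group (reporting only).
#' @param source One of `"workplace"`, `"transportation"`,
#'   `"cumulative"`.
#' @param n_boot Number of bootstrap samples (default 100).
#' @param seed Seed.
#' @return A one-row `ERRResult` data.frame: `group`, `source`, `err`,
#'   `ci_low`, `ci_high`, `n_bootstrap`.
#' @export
bootstrap_err <- function(data, group, source = c("workplace",
                                                  "transportation",
                                                  "cumulative"),
                          n_boot = 100, seed = 1L) {
  source <- match.arg(source)
  if (nrow(data) < 2L) stop("bootstrap requires at least 2 tracts")
  if (!is_count(n_boot)) stop_config("n_boot must be >= 1")
  one_err <- function(idx) {
    d <- data[idx, , drop = FALSE]
    if (source == "cumulative") {
      compute_cumulative_err(d$omega_work, d$omega_transport, d$p, d$t)
    } else {
      compute_err(d$omega, d$p, d$t)
    }
  }
  set.seed(substream_seed(seed, paste0("bootstrap:", group, ":", source)))
  n <- nrow(data)
  reps <- vapply(seq_len(n_boot), function(b) {
    tryCatch(one_err(sample.int(n, n, replace = TRUE)),
             error = function(e) NA_real_)
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  if (length(reps) == 0L) {
    warning(sprintf("all bootstrap replicates undefined for %s/%s",
                    group, source))
    return(data.frame(group = group, source = source, err = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      n_bootstrap = as.integer(n_boot),
                      stringsAsFactors = FALSE))
  }
  q <- pctl(reps, c(0.5, 0.025, 0.975))
  data.frame(group = group, source = source, err = q[1], ci_low = q[2],
             ci_high = q[3], n_bootstrap = as.integer(n_boot),
             stringsAsFactors = FALSE)
}

#' Flag tracts with cumulatively high workplace and transportation noise
#'
#' A tract is cumulatively high when it lies strictly above the 75th
#' percentile of both the workplace and the transportation exposure
#' prevalence distributions (percentiles taken over non-excluded tracts
#' nationwide). Per-tract percentile ranks are the empirical CDF values
#' (percent of tracts at or below the tract's prevalence).
#'
#' @param workplace,transport `PrevalenceEstimate` tables sharing tract
#'   ids.
#' @return A `CumulativeFlag` data.frame: `tract_id`,
#'   `workplace_pctile`, `transport_pctile`, `high_both`.
#' @export
classify_cumulative_high <- function(workplace, transport) {
  w <- workplace[!workplace$excluded & !is.na(workplace$omega),
                 c("tract_id", "omega")]
  t <- transport[!transport$excluded & !is.na(transport$omega),
                 c("tract_id", "omega")]
  names(w)[2] <- "omega_work"; names(t)[2] <- "omega_trans"
  d <- merge(w, t, by = "tract_id")
  cw <- pctl(d$omega_work, 0.75)
  ct <- pctl(d$omega_trans, 0.75)
  data.frame(tract_id = d$tract_id,
             workplace_pctile = 100 * stats::ecdf(d$omega_work)(d$omega_work),
             transport_pctile = 100 * stats::ecdf(d$omega_trans)(d$omega_trans),
             high_both = d$omega_work > cw & d$omega_trans > ct,
             stringsAsFactors = FALSE)
}

#' Stratum-specific quintile assignment
#'
#' Assigns each tract the quintile of `values` within its stratum
#' (metropolitan area, or the pooled nonmetropolitan stratum). Quintile
#' boundaries are the stratum's 20/40/60/80th percentiles (linear
#' interpolation between order statistics); bins are right-closed, so
#' ties share a quintile and an all-equal stratum collapses to
#' quintile 1. Strata with fewer than 5 tracts are assigned by the same
#' rank-band rule with a warning.
#'
#' @param values Tract-level proportions of the group of interest.
#' @param stratum Stratum label per tract.
#' @param tract_id Tract ids.
#' @param quiet Suppress the small-stratum warning.
#' @return A `QuintileAssignment` data.frame: `tract_id`, `quintile`
#'   (integer 1-5), `stratum`.
#' @export
assign_quintiles <- function(values, stratum, tract_id, quiet = FALSE) {
  stopifnot(length(values) == length(stratum),
            length(values) == length(tract_id))
  if (any(is.na(stratum)) || any(stratum == ""))
    stop("every tract needs a stratum label")
  q <- integer(length(values))
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    if (length(i) < 5L && !quiet)
      warning(sprintf("stratum '%s' has %d (<5) tracts; quintiles from rank bands",
                      s, length(i)))
    cuts <- pctl(values[i], c(0.2, 0.4, 0.6, 0.8))
    q[i] <- 1L + as.integer(rowSums(outer(values[i], cuts, `>`)))
  }
  data.frame(tract_id = tract_id, quintile = q, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' @rdname assign_quintiles
#' @param tracts Tract table; convenience wrapper computing the minority
#'   (or subgroup) proportion and the metro/nonmetro strata.
#' @param group `"minority"` for all non-NH-White residents combined, or
#'   one of the `pop_*` race column names.
#' @param mode `"per_metro"` (each metro its own stratum, nonmetro
#'   pooled; the default) or `"pooled"` (one metropolitan and one
#'   nonmetropolitan stratum).
#' @export
tract_quintiles <- function(tracts, group = "minority",
                            mode = c("per_metro", "pooled"), quiet = FALSE) {
  mode <- match.arg(mode)
  prop <- if (group == "minority") {
    1 - tracts$pop_nh_white / tracts$population
  } else {
    stopifnot(group %in% race_columns())
    tracts[[group]] / tracts$population
  }
  stratum <- if (mode == "per_metro") {
    ifelse(tracts$metro_id == "" | is.na(tracts$metro_id),
           "nonmetro", tracts$metro_id)
  } else {
    ifelse(tracts$metro_id == "" | is.na(tracts$metro_id),
           "nonmetro", "metro")
  }
  out <- assign_quintiles(prop, stratum, tracts$tract_id, quiet = quiet)
  out$group <- group
  out
}
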