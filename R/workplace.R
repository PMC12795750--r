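#' Monte Carlo exceedance probability for one occupational group
#'
#' Estimates `P(TWA > threshold)` for a job-exposure-matrix entry whose
#' 8-h time-weighted-average noise is normal on the dBA scale, by
#' direct simulation. Converges to the analytic normal tail
#' `1 - pnorm((threshold - mean)/sd)` (see [jem_exceedance()]).
#'
#' @param entry A one-row JEM entry (list/data.frame with `mean_twa`,
#'   `sd_twa`).
#' @param threshold Exceedance threshold in dBA (default 85, the NIOSH
#'   recommended exposure limit).
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Seed.
#' @return Estimated exceedance probability.
#' @export
group_exceedance_probability <- function(entry, threshold = 85,
                                         n_draws = 10000, seed = 1L) {
  if (!is_count(n_draws)) stop_config("n_draws must be a positive integer")
  if (entry$sd_twa <= 0) stop_config("sd_twa must be positive")
  set.seed(substream_seed(seed, "exceedance"))
  mean(stats::rnorm(n_draws, entry$mean_twa, entry$sd_twa) > threshold)
}

# Shared Monte Carlo summary: central estimate is the 50th percentile of
# the per-iteration exposed fractions, CI the 2.5th/97.5th percentiles.
mc_summary <- function(draws) {
  q <- pctl(draws, c(0.5, 0.025, 0.975))
  list(omega = q[1], ci_low = q[2], ci_high = q[3])
}

prevalence_row <- function(tract_id, source, omega = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_,
                           n_iterations = NA_integer_, excluded = FALSE,
                           exclusion_reason = "") {
  data.frame(tract_id = tract_id, source = source, omega = omega,
             ci_low = ci_low, ci_high = ci_high,
             n_iterations = n_iterations, excluded = excluded,
             exclusion_reason = exclusion_reason, stringsAsFactors = FALSE)
}

workplace_tract_draws <- function(emp, p_g, n_iterations) {
  total <- sum(emp)
  draws <- stats::rbinom(n_iterations * length(emp),
                         size = rep(emp, n_iterations),
                         prob = rep(p_g, n_iterations))
  colSums(matrix(draws, nrow = length(emp))) / total
}

#' Estimate a tract's workplace noise-exposure prevalence
#'
#' Monte Carlo estimate of the proportion of a tract's workers exposed
#' above the NIOSH recommended exposure limit. Each iteration draws, for
#' every occupational group, the number of exposed workers as
#' `Binomial(emp_g, p_g)` with `p_g` the group's normal-tail exceedance
#' probability (equivalent in distribution to thresholding one TWA draw
#' per worker), and records the employment-weighted exposed fraction.
#' The central estimate is the 50th percentile over iterations, with the
#' 2.5th/97.5th percentiles as the 95% interval. Tracts with 20 or
#' fewer workers are excluded (inclusive threshold).
#'
#' @param tract One tract row with `tract_id` and `emp_<group_id>`
#'   employment-count columns.
#' @param jem JEM table (`group_id`, `mean_twa`, `sd_twa`) covering
#'   every employment group present.
#' @param threshold Hazard threshold in dBA (default 85).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed Seed.
#' @param return_draws If `TRUE`, attach the per-iteration exposed
#'   fractions as attribute `"draws"` (used for CI propagation when
#'   aggregating).
#' @return A one-row `PrevalenceEstimate` data.frame: `tract_id`,
#'   `source`, `omega`, `ci_low`, `ci_high`, `n_iterations`, `excluded`,
#'   `exclusion_reason`.
#' @export
estimate_workplace_prevalence <- function(tract, jem, threshold = 85,
                                          n_iterations = 1000, seed = 1L,
                                          return_draws = FALSE) {
  if (!is_count(n_iterations)) stop_config("n_iterations must be >= 1")
  emp_cols <- grep("^emp_", names(tract), value = TRUE)
  groups <- sub("^emp_", "", emp_cols)
  emp <- as.numeric(tract[1, emp_cols])
  keep <- emp > 0  # zero-employment groups contribute nothing
  missing <- setdiff(groups[keep], jem$group_id)
  if (length(missing))
    stop(sprintf("JEM is missing occupational group(s): %s",
                 paste(missing, collapse = ", ")))
  total <- sum(emp)
  if (total <= 20) {
    return(prevalence_row(tract$tract_id, "workplace", excluded = TRUE,
                          exclusion_reason = "<=20 workers"))
  }
  emp <- emp[keep]
  idx <- match(groups[keep], jem$group_id)
  p_g <- jem_exceedance(jem$mean_twa[idx], jem$sd_twa[idx], threshold)
  set.seed(substream_seed(seed, paste0("workplace:", tract$tract_id)))
  om <- workplace_tract_draws(emp, p_g, n_iterations)
  s <- mc_summary(om)
  out <- prevalence_row(tract$tract_id, "workplace", s$omega, s$ci_low,
                        s$ci_high, as.integer(n_iterations))
  if (return_draws) attr(out, "draws") <- matrix(om, nrow = 1)
  out
}

#' @rdname estimate_workplace_prevalence
#' @param tracts Full tract table; one estimate per row.
#' @export
estimate_workplace_prevalence_all <- function(tracts, jem, threshold = 85,
                                              n_iterations = 1000, seed = 1L,
                                              return_draws = FALSE) {
  rows <- lapply(seq_len(nrow(tracts)), function(i)
    estimate_workplace_prevalence(tracts[i, , drop = FALSE], jem, threshold,
                                  n_iterations, seed, return_draws))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (return_draws) {
    dr <- do.call(rbind, lapply(rows, function(r)
      attr(r, "draws") %||% matrix(NA_real_, 1, n_iterations)))
    attr(out, "draws") <- dr
  }
  out
}
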