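#' Configuration for the transportation-noise Monte Carlo
#'
#' @param threshold Exposure threshold in dBA of 24-h L_Aeq (default
#'   55; exposure uses the strict inequality `> threshold`).
#' @param level_uncertainty_sd Standard deviation in dBA of the normal
#'   perturbation applied to each block level per iteration (default 2;
#'   0 gives the deterministic aggregation).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed Seed.
#' @return A list of class `noisequity_transport_config`.
#' @export
transport_config <- function(threshold = 55, level_uncertainty_sd = 2,
                             n_iterations = 1000, seed = 1L) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_config("threshold must be positive")
  if (!is.numeric(level_uncertainty_sd) || level_uncertainty_sd < 0)
    stop_config("level_uncertainty_sd must be >= 0")
  if (!is_count(n_iterations)) stop_config("n_iterations must be >= 1")
  structure(list(threshold = threshold,
                 level_uncertainty_sd = level_uncertainty_sd,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "noisequity_transport_config")
}

#' Estimate a tract's transportation noise-exposure prevalence
#'
#' Population-weighted Monte Carlo aggregation of block-level 24-h
#' L_Aeq up to the tract. Each iteration perturbs every block's level
#' with independent normal noise of sd `level_uncertainty_sd`, classes a
#' block's entire population as exposed when the perturbed level is
#' strictly above the threshold, and records the population-weighted
#' exposed fraction. The central estimate is the 50th percentile over
#' iterations with 2.5th/97.5th percentile bounds; with zero
#' uncertainty the estimate is the exact deterministic population
#' fraction in blocks above the threshold. Tracts with 20 or fewer
#' residents are excluded.
#'
#' @param blocks Block rows of a single tract (`tract_id`, `population`,
#'   `laeq_24h`).
#' @param config A [transport_config()].
#' @param return_draws Attach per-iteration exposed fractions as
#'   attribute `"draws"`.
#' @return A one-row `PrevalenceEstimate` data.frame (see
#'   [estimate_workplace_prevalence()]).
#' @export
estimate_transport_prevalence <- function(blocks, config = transport_config(),
                                          return_draws = FALSE) {
  stopifnot(nrow(blocks) >= 1)
  if (any(blocks$population < 0)) stop_config("block populations must be >= 0")
  tract_id <- blocks$tract_id[1]
  pop <- blocks$population
  total <- sum(pop)
  if (total == 0) {
    return(prevalence_row(tract_id, "transportation", excluded = TRUE,
                          exclusion_reason = "zero population"))
  }
  if (total <= 20) {
    return(prevalence_row(tract_id, "transportation", excluded = TRUE,
                          exclusion_reason = "<=20 residents"))
  }
  n_it <- config$n_iterations
  if (config$level_uncertainty_sd == 0) {
    om <- rep(sum(pop[blocks$laeq_24h > config$threshold]) / total, n_it)
  } else {
    set.seed(substream_seed(config$seed, paste0("transport:", tract_id)))
    eps <- matrix(stats::rnorm(length(pop) * n_it, 0,
                               config$level_uncertainty_sd),
                  nrow = length(pop))
    exposed <- (blocks$laeq_24h + eps) > config$threshold
    om <- as.numeric(crossprod(pop, exposed)) / total
  }
  s <- mc_summary(om)
  out <- prevalence_row(tract_id, "transportation", s$omega, s$ci_low,
                        s$ci_high, n_it)
  if (return_draws) attr(out, "draws") <- matrix(om, nrow = 1)
  out
}

#' @rdname estimate_transport_prevalence
#' @param blocks_all Block table covering many tracts.
#' @export
estimate_transport_prevalence_all <- function(blocks_all,
                                              config = transport_config(),
                                              return_draws = FALSE) {
  split_blocks <- split(blocks_all, blocks_all$tract_id)
  rows <- lapply(split_blocks, estimate_transport_prevalence, config = config,
                 return_draws = return_draws)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (return_draws) {
    dr <- do.call(rbind, lapply(rows, function(r)
      attr(r, "draws") %||% matrix(NA_real_, 1, config$n_iterations)))
    attr(out, "draws") <- dr
  }
  out
}

#' Aggregate tract prevalences to county, metro or nationwide level
#'
#' The exposed count at a level is the population-weighted sum
#' `sum(pop_i * omega_i)` over non-excluded tracts, and the percentage
#' is `100 * count / sum(pop_i)`. The CI is propagated by summing
#' per-iteration draws when a draws matrix is available, otherwise by
#' the delta method on per-tract CIs (tracts treated as independent,
#' per-tract SE = CI width / 3.92).
#'
#' @param prevalences A `PrevalenceEstimate` table.
#' @param populations Per-tract denominators aligned with
#'   `prevalences` rows (residents or workers).
#' @param by Optional grouping vector (county/metro ids) for sub-level
#'   aggregation; `NULL` aggregates everything to one row.
#' @param draws Optional tracts-by-iterations matrix of exposed
#'   fractions aligned with `prevalences` rows.
#' @return A data.frame with `group`, `exposed`, `percent`,
#'   `exposed_low`, `exposed_high`, `percent_low`, `percent_high`,
#'   `population`.
#' @export
aggregate_exposed <- function(prevalences, populations, by = NULL,
                              draws = NULL) {
  if (nrow(prevalences) == 0L) stop("no prevalence estimates to aggregate")
  stopifnot(length(populations) == nrow(prevalences))
  keep <- !prevalences$excluded & !is.na(prevalences$omega)
  if (!any(keep)) stop("no non-excluded prevalence estimates present")
  if (is.null(by)) by <- rep("nationwide", nrow(prevalences))
  stopifnot(length(by) == nrow(prevalences))
  groups <- unique(by[keep])
  out <- lapply(groups, function(g) {
    i <- which(keep & by == g)
    pop <- populations[i]
    om <- prevalences$omega[i]
    count <- sum(pop * om)
    total <- sum(pop)
    if (!is.null(draws)) {
      # median of the per-iteration totals: the sum of per-tract medians
      # is not bracketed by the totals' percentiles when many tracts are
      # zero-inflated, so the central estimate follows the same
      # 50th-percentile convention as the CI
      cnt_k <- as.numeric(crossprod(pop, draws[i, , drop = FALSE]))
      count <- pctl(cnt_k, 0.5)
      lo <- pctl(cnt_k, 0.025); hi <- pctl(cnt_k, 0.975)
    } else {
      se_i <- (prevalences$ci_high[i] - prevalences$ci_low[i]) / 3.92
      se <- sqrt(sum((pop * se_i)^2))
      lo <- count - 1.96 * se; hi <- count + 1.96 * se
    }
    data.frame(group = g, exposed = count, percent = 100 * count / total,
               exposed_low = lo, exposed_high = hi,
               percent_low = 100 * lo / total,
               percent_high = 100 * hi / total,
               population = total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percentage of a population exposed
#'
#' Plain percentage arithmetic `100 * exposed / total`, used when
#' turning aggregated exposed counts into the percentages quoted in
#' reports.
#'
#' @param exposed Exposed count.
#' @param total Total population.
#' @return `100 * exposed / total`.
#' @export
exposed_percentage <- function(exposed, total) {
  stopifnot(total > 0)
  100 * exposed / total
}
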