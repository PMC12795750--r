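#' Generate synthetic redlining and mortgage-lending tables
#'
#' Emulates the two structural-racism inputs. A `redline_fraction` of
#' urban tracts (RUCA 1-3) receive HOLC grade-overlap proportions
#' (grades A-D), sampled preferentially from high-minority tracts and
#' with the D-grade share increasing in minority proportion. For every
#' redlined tract a mortgage table row is produced; a
#' `discrimination_fraction` of redlined tracts are designated for
#' discriminatory lending and receive loan counts constructed so their
#' mortgage-discrimination index D is strictly below 1, while the
#' remaining redlined tracts get proportional lending (D >= 1, near 1).
#'
#' @param tracts Tract table from [generate_geography()].
#' @param config The same [generator_config()].
#' @return A list with `holc` (tract_id, overlap_a..overlap_d,
#'   total_graded) and `mortgage` (tract_id, loans_minority,
#'   loans_total, households_minority, households_total).
#' @export
generate_structural <- function(tracts, config) {
  validate_generator_config(config)
  set.seed(substream_seed(config$seed, "structural"))
  empty_holc <- data.frame(tract_id = character(), overlap_a = numeric(),
                           overlap_b = numeric(), overlap_c = numeric(),
                           overlap_d = numeric(), total_graded = numeric(),
                           stringsAsFactors = FALSE)
  empty_mort <- data.frame(tract_id = character(), loans_minority = integer(),
                           loans_total = integer(),
                           households_minority = integer(),
                           households_total = integer(),
                           stringsAsFactors = FALSE)
  urban <- which(tracts$ruca_code <= 3)
  n_red <- round(config$redline_fraction * length(urban))
  if (n_red == 0L) return(list(holc = empty_holc, mortgage = empty_mort))

  m_prop <- 1 - tracts$pop_nh_white / tracts$population
  # redlining preferentially hits high-minority urban tracts
  w <- (rank(m_prop[urban]) / length(urban))^2
  red <- sort(sample(urban, n_red, prob = w))
  m_red <- m_prop[red]
  nr <- length(red)

  # ~8% of redlined tracts fall below the 20% overlap floor so the HRS
  # missingness rule is exercised
  total_graded <- ifelse(stats::runif(nr) < 0.08,
                         stats::runif(nr, 0.05, 0.19),
                         stats::runif(nr, 0.25, 1.0))
  wa <- pmax(0.05, 1.5 * (1 - m_red))
  wb <- pmax(0.05, 1.2 * (1 - m_red) + 0.3)
  wc <- 1 + m_red
  wd <- 0.5 + 3 * m_red
  wsum <- wa + wb + wc + wd
  holc <- data.frame(tract_id = tracts$tract_id[red],
                     overlap_a = total_graded * wa / wsum,
                     overlap_b = total_graded * wb / wsum,
                     overlap_c = total_graded * wc / wsum,
                     overlap_d = total_graded * wd / wsum,
                     total_graded = total_graded,
                     stringsAsFactors = FALSE)

  h_total <- pmax(10L, round(tracts$population[red] / 2.6))
  h_min <- pmax(1L, round(m_red * h_total))
  l_total <- pmax(5L, round(h_total * stats::runif(nr, 0.25, 0.45)))
  designated <- stats::runif(nr) < config$discrimination_fraction
  ratio <- ifelse(designated, stats::runif(nr, 0.45, 0.85),
                  stats::runif(nr, 1.0, 1.06))
  l_min <- round(ratio * (h_min / h_total) * l_total)
  l_min <- pmin(l_min, l_total)
  # enforce the designation exactly on the *computed* index
  d_idx <- (l_min / l_total) / (h_min / h_total)
  bump_dn <- designated & d_idx >= 1
  l_min[bump_dn] <- pmax(0L, ceiling((h_min[bump_dn] / h_total[bump_dn]) *
                                       l_total[bump_dn]) - 1L)
  bump_up <- !designated & (l_min / l_total) / (h_min / h_total) < 1
  l_min[bump_up] <- pmin(l_total[bump_up],
                         ceiling((h_min[bump_up] / h_total[bump_up]) *
                                   l_total[bump_up]))
  mortgage <- data.frame(tract_id = tracts$tract_id[red],
                         loans_minority = as.integer(l_min),
                         loans_total = as.integer(l_total),
                         households_minority = as.integer(h_min),
                         households_total = as.integer(h_total),
                         stringsAsFactors = FALSE)
  list(holc = holc, mortgage = mortgage)
}
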