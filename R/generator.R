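#' Configuration for the synthetic census-geography generator
#'
#' Collects every knob of the synthetic data-generating process:
#' geography sizes, the strength of spatial clustering of minority
#' composition, the two structural effect sizes (on block noise levels
#' and on occupational sorting), redlining/discrimination coverage, and
#' the master seed. The defaults describe a mid-size stated world:
#' minority composition spatially clustered within metro areas, a 5 dBA
#' shift in mean block noise per unit minority proportion, a one-unit
#' log-odds shift toward noisy occupations per unit minority proportion,
#' 30% of urban tracts covered by 1930s HOLC grades and half of those
#' subject to discriminatory 1990s lending.
#'
#' @param n_metro_areas Number of metropolitan areas (>= 1).
#' @param tracts_per_metro Census tracts per metro area (>= 1).
#' @param nonmetro_tracts Tracts in the pooled nonmetropolitan stratum.
#' @param blocks_per_tract Integer range `c(min, max)` of census blocks
#'   per tract.
#' @param mean_tract_population Mean tract population (persons).
#' @param minority_cluster_strength Spatial autocorrelation strength
#'   (logit-scale amplitude) of minority proportion within metros, >= 0.
#' @param beta_transport Shift in mean block 24-h L_Aeq (dBA) per unit
#'   tract minority proportion.
#' @param beta_occupation Log-odds shift toward noisy occupational
#'   groups per unit tract minority proportion.
#' @param redline_fraction Proportion of urban tracts given HOLC
#'   grade coverage, in `[0, 1]`.
#' @param discrimination_fraction Proportion of redlined tracts with
#'   mortgage-discrimination index D < 1, in `[0, 1]`.
#' @param seed Master seed; per-table sub-streams are derived from it.
#' @return A list of class `noisequity_generator_config`.
#' @export
generator_config <- function(n_metro_areas = 5,
                             tracts_per_metro = 60,
                             nonmetro_tracts = 100,
                             blocks_per_tract = c(4L, 12L),
                             mean_tract_population = 4000,
                             minority_cluster_strength = 1.5,
                             beta_transport = 5,
                             beta_occupation = 1,
                             redline_fraction = 0.3,
                             discrimination_fraction = 0.5,
                             seed = 1L) {
  cfg <- list(n_metro_areas = n_metro_areas,
              tracts_per_metro = tracts_per_metro,
              nonmetro_tracts = nonmetro_tracts,
              blocks_per_tract = as.integer(blocks_per_tract),
              mean_tract_population = mean_tract_population,
              minority_cluster_strength = minority_cluster_strength,
              beta_transport = beta_transport,
              beta_occupation = beta_occupation,
              redline_fraction = redline_fraction,
              discrimination_fraction = discrimination_fraction,
              seed = as.integer(seed))
  class(cfg) <- "noisequity_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  for (f in c("n_metro_areas", "tracts_per_metro", "nonmetro_tracts",
              "mean_tract_population")) {
    if (!is_count(cfg[[f]]))
      stop_config(sprintf("'%s' must be a positive integer, got %s",
                          f, deparse(cfg[[f]])))
  }
  b <- cfg$blocks_per_tract
  if (length(b) != 2L || any(!is.finite(b)) || b[1] < 1 || b[2] < b[1])
    stop_config("'blocks_per_tract' must be an increasing range with min >= 1")
  if (!is.numeric(cfg$minority_cluster_strength) ||
      cfg$minority_cluster_strength < 0)
    stop_config("'minority_cluster_strength' must be >= 0")
  for (f in c("redline_fraction", "discrimination_fraction")) {
    if (!is_prob(cfg[[f]]))
      stop_config(sprintf("'%s' must lie in [0, 1]", f))
  }
  invisible(cfg)
}

# Baseline employment shares across the 22 major occupational groups,
# loosely following the national workforce mix.
base_employment_shares <- function() {
  s <- c(0.110, 0.050, 0.030, 0.020, 0.010, 0.017, 0.012, 0.060, 0.020,
         0.060, 0.030, 0.022, 0.060, 0.040, 0.030, 0.100, 0.120, 0.007,
         0.055, 0.033, 0.060, 0.065)
  s / sum(s)
}

# Within-tract standard deviation of block L_Aeq around the tract mean,
# and the 8-h TWA model used for ground-truth expectation. Fixed scalars
# of the stated world, documented in the methods vignette.
BLOCK_LAEQ_SD <- 3
LAEQ_BASE_NONURBAN <- 47
LAEQ_URBAN_BUMP <- 3.5
LAEQ_TRACT_SD <- 1.5

race_columns <- function() {
  c("pop_nh_white", "pop_nh_black", "pop_hispanic",
    "pop_nh_asian", "pop_nh_aian", "pop_nh_nhpi")
}

minority_columns <- function() setdiff(race_columns(), "pop_nh_white")

#' Generate a synthetic census geography
#'
#' Draws a full synthetic tract/block geography from the configured
#' data-generating process: tracts are laid out on jittered grids within
#' metro areas plus a scattered nonmetropolitan stratum; minority
#' proportion is spatially autocorrelated within metros (a smooth
#' logit-scale field of strength `minority_cluster_strength`);
#' employment is allocated across the 22 major occupational groups with
#' the log-odds of noisy groups shifted by `beta_occupation` times the
#' minority proportion; and block 24-h L_Aeq levels are normal around a
#' tract mean shifted by `beta_transport` times the minority proportion.
#' The returned ground truth records the configured effect sizes, each
#' tract's analytically expected workplace and transportation exposure
#' prevalence, and the crude Q5-vs-Q1 log odds of cumulative-high
#' exposure implied by those expectations.
#'
#' @param config A [generator_config()].
#' @return A list with elements `tracts` (one row per tract), `blocks`
#'   (one row per block, populations partitioning the tract total) and
#'   `ground_truth` (never consumed by the analysis stages).
#' @export
generate_geography <- function(config) {
  validate_generator_config(config)
  soc <- soc_groups()
  n_groups <- nrow(soc)
  emp_cols <- paste0("emp_", soc$group_id)

  ## ---- tract-level draws ----
  set.seed(substream_seed(config$seed, "tracts"))
  n_metro <- config$n_metro_areas
  metro_ids <- sprintf("m%02d", seq_len(n_metro))
  metro_lat <- stats::runif(n_metro, 27, 46)
  metro_lon <- stats::runif(n_metro, -121, -72)
  metro_base_minority <- stats::runif(n_metro, 0.2, 0.5)

  tract_list <- vector("list", n_metro + 1L)
  for (m in seq_len(n_metro)) {
    nt <- config$tracts_per_metro
    side <- ceiling(sqrt(nt))
    gx <- (seq_len(nt) - 1L) %% side
    gy <- (seq_len(nt) - 1L) %/% side
    lat <- metro_lat[m] + (gy - side / 2) * 0.012 + stats::rnorm(nt, 0, 0.002)
    lon <- metro_lon[m] + (gx - side / 2) * 0.012 + stats::rnorm(nt, 0, 0.002)
    # smooth minority field: Gaussian kernel around a random urban core
    core <- c(stats::runif(1, 0, side), stats::runif(1, 0, side))
    d2 <- (gx - core[1])^2 + (gy - core[2])^2
    r2 <- (side / 3)^2
    field <- exp(-d2 / (2 * r2))
    eta <- stats::qlogis(metro_base_minority[m]) +
      config$minority_cluster_strength * (2 * field - mean(2 * field)) +
      stats::rnorm(nt, 0, 0.4)
    tract_list[[m]] <- data.frame(
      tract_id = sprintf("%s-t%03d", metro_ids[m], seq_len(nt)),
      metro_id = metro_ids[m],
      ruca_code = sample(1:3, nt, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      minority_prop = stats::plogis(eta),
      centroid_lat = lat, centroid_lon = lon,
      stringsAsFactors = FALSE)
  }
  nn <- config$nonmetro_tracts
  # nonmetro minority shares drawn from the same marginal distribution as
  # the metro base so that urbanicity is independent of composition under
  # the null configuration
  eta_nm <- stats::qlogis(stats::runif(nn, 0.2, 0.5)) + stats::rnorm(nn, 0, 0.4)
  tract_list[[n_metro + 1L]] <- data.frame(
    tract_id = sprintf("nm-t%04d", seq_len(nn)),
    metro_id = "",
    ruca_code = sample(4:10, nn, replace = TRUE),
    minority_prop = stats::plogis(eta_nm),
    centroid_lat = stats::runif(nn, 27, 46),
    centroid_lon = stats::runif(nn, -121, -72),
    stringsAsFactors = FALSE)
  tr <- do.call(rbind, tract_list)
  n <- nrow(tr)
  m_prop <- tr$minority_prop
  urban <- tr$ruca_code <= 3

  tr$population <- pmax(30L, stats::rpois(n, config$mean_tract_population *
                                               exp(stats::rnorm(n, 0, 0.3))))
  # racial/ethnic composition: White = 1 - minority; minority split by a
  # jittered Dirichlet over the five minority groups
  alpha <- c(4, 5, 2, 0.4, 0.2)  # Black, Hispanic, Asian, AI/AN, NH/PI
  gmat <- matrix(stats::rgamma(n * 5L, shape = rep(alpha, each = n)), nrow = n)
  split <- gmat / rowSums(gmat)
  probs <- cbind(1 - m_prop, split * m_prop)
  race <- t(vapply(seq_len(n),
                   function(i) stats::rmultinom(1, tr$population[i], probs[i, ])[, 1],
                   integer(6L)))
  colnames(race) <- race_columns()
  tr <- cbind(tr, as.data.frame(race))

  tr$workers <- stats::rbinom(n, tr$population, stats::runif(n, 0.38, 0.55))
  base_share <- base_employment_shares()
  noisy <- soc$noisy
  emp <- matrix(0L, n, n_groups, dimnames = list(NULL, emp_cols))
  for (i in seq_len(n)) {
    lg <- log(base_share) + config$beta_occupation * m_prop[i] * noisy
    p <- exp(lg) / sum(exp(lg))
    emp[i, ] <- stats::rmultinom(1, tr$workers[i], p)[, 1]
  }
  tr <- cbind(tr, as.data.frame(emp))

  tr$pct_unemployed <- stats::plogis(stats::qlogis(0.05) +
                                     1.2 * (m_prop - 0.35) +
                                     stats::rnorm(n, 0, 0.3))
  tr$pct_low_income <- stats::plogis(stats::qlogis(0.25) +
                                     1.5 * (m_prop - 0.35) +
                                     stats::rnorm(n, 0, 0.3))
  tr$pct_no_diploma <- stats::plogis(stats::qlogis(0.12) +
                                     1.3 * (m_prop - 0.35) +
                                     stats::rnorm(n, 0, 0.3))
  tr$pop_density <- exp(ifelse(urban,
                               stats::rnorm(n, log(1500), 0.7),
                               stats::rnorm(n, log(40), 0.8)))

  # tract-level mean L_Aeq: urban bump plus the configured composition shift
  mu_laeq <- LAEQ_BASE_NONURBAN + LAEQ_URBAN_BUMP * urban +
    config$beta_transport * m_prop + stats::rnorm(n, 0, LAEQ_TRACT_SD)

  ## ---- block-level draws (own sub-stream) ----
  set.seed(substream_seed(config$seed, "blocks"))
  k <- sample(seq(config$blocks_per_tract[1], config$blocks_per_tract[2]),
              n, replace = TRUE)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    ki <- k[i]
    bp <- stats::rmultinom(1, tr$population[i], rep(1 / ki, ki))[, 1]
    blocks[[i]] <- data.frame(
      block_id = sprintf("%s-b%02d", tr$tract_id[i], seq_len(ki)),
      tract_id = tr$tract_id[i],
      population = bp,
      laeq_24h = stats::rnorm(ki, mu_laeq[i], BLOCK_LAEQ_SD),
      stringsAsFactors = FALSE)
  }
  bl <- do.call(rbind, blocks)
  rownames(bl) <- NULL
  rownames(tr) <- NULL

  ## ---- ground truth ----
  jem <- generate_jem(soc$group_id)
  p_g <- jem_exceedance(jem$mean_twa, jem$sd_twa, 85)
  emp_tot <- rowSums(emp)
  exp_work <- as.numeric(emp %*% p_g) / ifelse(emp_tot > 0, emp_tot, NA_real_)
  exp_trans <- stats::pnorm(55, mu_laeq, BLOCK_LAEQ_SD, lower.tail = FALSE)
  gt <- list(
    beta_transport = config$beta_transport,
    beta_occupation = config$beta_occupation,
    tracts = data.frame(tract_id = tr$tract_id,
                        expected_workplace_prev = exp_work,
                        expected_transport_prev = exp_trans,
                        stringsAsFactors = FALSE),
    true_q5_logodds = implied_q5_logodds(tr, exp_work, exp_trans))
  list(tracts = tr, blocks = bl, ground_truth = gt)
}

# Crude Q5-vs-Q1 log odds of cumulative-high exposure implied by the
# analytically expected prevalences (continuity-corrected).
implied_q5_logodds <- function(tracts, exp_work, exp_trans) {
  ok <- is.finite(exp_work) & is.finite(exp_trans)
  flag <- exp_work > pctl(exp_work[ok], 0.75) &
    exp_trans > pctl(exp_trans[ok], 0.75)
  stratum <- ifelse(tracts$metro_id == "", "nonmetro", tracts$metro_id)
  q <- assign_quintiles(1 - tracts$pop_nh_white / tracts$population,
                        stratum, tracts$tract_id, quiet = TRUE)$quintile
  tab <- function(qq) {
    a <- sum(flag[ok & q == qq]) + 0.5
    b <- sum(!flag[ok & q == qq]) + 0.5
    a / b
  }
  log(tab(5L) / tab(1L))
}

#' Permutation test for rank correlation
#'
#' Two-sided permutation test of the Spearman rank correlation between
#' two vectors, used as the generator's own independent check that a
#' configured composition effect is (or is not) present in its output.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return A list with `rho` (observed Spearman correlation) and
#'   `p_value` (permutation p-value, add-one corrected).
#' @export
permutation_cor_test <- function(x, y, n_perm = 1000, seed = 1L) {
  stopifnot(length(x) == length(y), n_perm >= 1)
  obs <- stats::cor(x, y, method = "spearman")
  set.seed(substream_seed(seed, "permutation"))
  ry <- rank(y)
  rx <- rank(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    r <- stats::cor(rx, sample(ry))
    if (abs(r) >= abs(obs)) hits <- hits + 1L
  }
  list(rho = obs, p_value = (hits + 1) / (n_perm + 1))
}
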