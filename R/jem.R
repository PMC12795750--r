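#' Major occupational groups used by the synthetic job-exposure matrix
#'
#' Returns the 22 major occupational groups (mirroring the major SOC
#' groups reported by the American Community Survey) together with the
#' canonical 8-h time-weighted-average (TWA) noise parameters the
#' synthetic generator assigns to each: a mean and standard deviation in
#' dBA, and a flag marking the conventionally "noisy" trades
#' (construction, production, transportation, installation/repair,
#' farming, grounds maintenance).
#'
#' @return A data.frame with columns `group_id`, `group_name`,
#'   `mean_twa`, `sd_twa`, `noisy`.
#' @export
soc_groups <- function() {
  g <- data.frame(
    group_id = sprintf("g%02d", 1:22),
    group_name = c(
      "management", "business_financial", "computer_mathematical",
      "architecture_engineering", "life_physical_social_science",
      "community_social_service", "legal", "education_library",
      "arts_entertainment_media", "healthcare_practitioners",
      "healthcare_support", "protective_service", "food_preparation",
      "building_grounds_maintenance", "personal_care", "sales",
      "office_administrative", "farming_fishing_forestry",
      "construction_extraction", "installation_maintenance_repair",
      "production", "transportation_material_moving"),
    mean_twa = c(72, 70, 70, 78, 74, 71, 68, 72, 75, 74, 73, 79, 78,
                 81, 72, 73, 70, 84, 87, 86, 85, 84),
    sd_twa = c(4, 3, 3, 5, 4, 3, 3, 3, 5, 4, 4, 5, 4,
               5, 4, 4, 3, 6, 5, 5, 6, 6),
    noisy = FALSE,
    stringsAsFactors = FALSE
  )
  g$noisy[g$group_name %in% c(
    "farming_fishing_forestry", "construction_extraction",
    "installation_maintenance_repair", "production",
    "transportation_material_moving", "building_grounds_maintenance")] <- TRUE
  g
}

#' Generate a noise job-exposure matrix
#'
#' Builds a job-exposure matrix (JEM) giving, for each occupational
#' group, the mean and standard deviation of 8-h TWA noise exposure in
#' dBA. When called with the canonical 22 major groups (the default) the
#' canonical parameters from [soc_groups()] are used; for an arbitrary
#' group list, parameters alternate between a quiet profile (mean 70
#' dBA) and a noisy profile (mean 87 dBA) so that the matrix always
#' contains at least one group near or above the 85 dBA hazard threshold
#' and one well below it.
#'
#' @param groups Character vector of occupational group ids (>= 2).
#' @param config Optional [generator_config()]; accepted for interface
#'   symmetry with the other generator stages (the JEM is deterministic).
#' @return A data.frame with columns `group_id`, `mean_twa`, `sd_twa`.
#' @export
generate_jem <- function(groups = soc_groups()$group_id, config = NULL) {
  if (length(groups) == 0L) stop_config("JEM requires a non-empty group list")
  if (length(groups) < 2L) stop_config("JEM requires at least 2 groups")
  canon <- soc_groups()
  if (all(groups %in% canon$group_id)) {
    out <- canon[match(groups, canon$group_id),
                 c("group_id", "mean_twa", "sd_twa")]
    rownames(out) <- NULL
    return(out)
  }
  n <- length(groups)
  noisy <- seq_len(n) %% 2L == 0L  # every second group noisy; >=1 of each
  data.frame(
    group_id = as.character(groups),
    mean_twa = ifelse(noisy, 87, 70),
    sd_twa = ifelse(noisy, 5, 3),
    stringsAsFactors = FALSE
  )
}

#' Analytic probability that a group's TWA exceeds a threshold
#'
#' Closed-form normal-tail exceedance `1 - pnorm((threshold - mean)/sd)`
#' for a JEM entry; the analytic counterpart of
#' [group_exceedance_probability()].
#'
#' @param mean_twa,sd_twa Normal TWA parameters in dBA (`sd_twa > 0`).
#' @param threshold Exceedance threshold in dBA (default 85, the NIOSH
#'   recommended exposure limit).
#' @return Exceedance probability (vectorized).
#' @export
jem_exceedance <- function(mean_twa, sd_twa, threshold = 85) {
  if (any(sd_twa <= 0)) stop_config("sd_twa must be positive")
  stats::pnorm(threshold, mean = mean_twa, sd = sd_twa, lower.tail = FALSE)
}
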