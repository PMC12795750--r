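# Small in-code fixtures shared across the suite.

# A tract row with employment concentrated in the named groups.
make_tract <- function(tract_id = "t1", emp = c(g01 = 100), workers = NULL,
                       population = 4000) {
  all_groups <- soc_groups()$group_id
  counts <- stats::setNames(rep(0L, length(all_groups)), all_groups)
  counts[names(emp)] <- emp
  df <- data.frame(tract_id = tract_id, population = population,
                   workers = workers %||% sum(emp),
                   stringsAsFactors = FALSE)
  for (g in all_groups) df[[paste0("emp_", g)]] <- counts[[g]]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_blocks <- function(tract_id = "t1", populations, laeq) {
  data.frame(block_id = sprintf("%s-b%02d", tract_id,
                                seq_along(populations)),
             tract_id = tract_id, population = populations,
             laeq_24h = laeq, stringsAsFactors = FALSE)
}

make_prevalence <- function(tract_id, omega, source = "workplace") {
  data.frame(tract_id = tract_id, source = source, omega = omega,
             ci_low = omega, ci_high = omega,
             n_iterations = 1L, excluded = FALSE, exclusion_reason = "",
             stringsAsFactors = FALSE)
}

# Mid-size geography reused by several regression tests (built once).
shared_geo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_metro_areas = 3, tracts_per_metro = 50,
                              nonmetro_tracts = 50,
                              blocks_per_tract = c(6L, 14L), seed = 42L)
      cache <<- generate_geography(cfg)
    }
    cache
  }
})
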