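test_that("identical config and seed reproduce identical tables", {
  cfg <- generator_config(n_metro_areas = 2, tracts_per_metro = 20,
                          nonmetro_tracts = 15, seed = 101L)
  g1 <- generate_geography(cfg)
  g2 <- generate_geography(cfg)
  expect_identical(g1$tracts, g2$tracts)
  expect_identical(g1$blocks, g2$blocks)
  s1 <- generate_structural(g1$tracts, cfg)
  s2 <- generate_structural(g2$tracts, cfg)
  expect_identical(s1, s2)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_metro_areas = 0), class = "noisequity_config_error")
  expect_error(generator_config(redline_fraction = 1.2),
               class = "noisequity_config_error")
  expect_error(generator_config(blocks_per_tract = c(5, 2)),
               class = "noisequity_config_error")
})

test_that("block populations partition tract populations exactly", {
  g <- shared_geo()
  sums <- tapply(g$blocks$population, g$blocks$tract_id, sum)
  expect_identical(as.integer(sums[g$tracts$tract_id]),
                   as.integer(g$tracts$population))
  expect_identical(unname(rowSums(g$tracts[, c("pop_nh_white", "pop_nh_black",
                                               "pop_hispanic", "pop_nh_asian",
                                               "pop_nh_aian", "pop_nh_nhpi")])),
                   as.numeric(g$tracts$population))
  expect_true(all(g$tracts$workers <= g$tracts$population))
})

test_that("null configuration decouples composition from block noise", {
  cfg <- generator_config(n_metro_areas = 10, tracts_per_metro = 150,
                          nonmetro_tracts = 500, beta_transport = 0,
                          beta_occupation = 0, seed = 202L)
  g <- generate_geography(cfg)
  mean_laeq <- tapply(g$blocks$laeq_24h, g$blocks$tract_id, mean)
  m <- 1 - g$tracts$pop_nh_white / g$tracts$population
  r <- cor(m, unname(mean_laeq[g$tracts$tract_id]))
  expect_lt(abs(r), 0.1)
})

test_that("configured transport effect is detected by the permutation check", {
  cfg <- generator_config(n_metro_areas = 10, tracts_per_metro = 150,
                          nonmetro_tracts = 500, beta_transport = 5,
                          seed = 303L)
  g <- generate_geography(cfg)
  exceed <- tapply(g$blocks$laeq_24h > 55, g$blocks$tract_id, mean)
  m <- 1 - g$tracts$pop_nh_white / g$tracts$population
  res <- permutation_cor_test(m, unname(exceed[g$tracts$tract_id]),
                              n_perm = 1000, seed = 7L)
  expect_gt(res$rho, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("JEM generation satisfies its contracts", {
  expect_error(generate_jem(character(0)), class = "noisequity_config_error")
  two <- generate_jem(c("alpha", "beta"))
  expect_identical(nrow(two), 2L)
  expect_true(all(two$sd_twa > 0))
  expect_true(any(two$mean_twa >= 85) && any(two$mean_twa < 80))
  canon <- generate_jem()
  expect_identical(nrow(canon), 22L)
  # analytic normal-tail exceedance: quiet group essentially never above
  # the limit, noisy group at the closed-form value
  expect_lt(jem_exceedance(70, 3, 85), 1e-6)
  expect_equal(jem_exceedance(87, 5, 85), 1 - pnorm((85 - 87) / 5),
               tolerance = 1e-12)
  expect_equal(jem_exceedance(87, 5, 85), 0.655, tolerance = 5e-3)
})

test_that("structural generator honors coverage and discrimination fractions", {
  g <- shared_geo()
  cfg0 <- generator_config(n_metro_areas = 3, tracts_per_metro = 50,
                           nonmetro_tracts = 50, redline_fraction = 0,
                           seed = 42L)
  s0 <- generate_structural(g$tracts, cfg0)
  expect_identical(nrow(s0$holc), 0L)

  cfg1 <- generator_config(n_metro_areas = 3, tracts_per_metro = 50,
                           nonmetro_tracts = 50, redline_fraction = 0.6,
                           discrimination_fraction = 1, seed = 42L)
  s1 <- generate_structural(g$tracts, cfg1)
  d1 <- compute_mortgage_discrimination(s1$mortgage$loans_minority,
                                        s1$mortgage$loans_total,
                                        s1$mortgage$households_minority,
                                        s1$mortgage$households_total)
  expect_true(all(d1 < 1))
  # HOLC overlap correlates positively with minority share
  m <- 1 - g$tracts$pop_nh_white / g$tracts$population
  red <- g$tracts$tract_id %in% s1$holc$tract_id
  expect_gt(mean(m[red]), mean(m[g$tracts$ruca_code <= 3 & !red]))
})

test_that("discrimination_fraction = 0.5 designates about half of redlined tracts", {
  cfg <- generator_config(n_metro_areas = 8, tracts_per_metro = 140,
                          nonmetro_tracts = 10, redline_fraction = 0.5,
                          discrimination_fraction = 0.5, seed = 404L)
  g <- generate_geography(cfg)
  s <- generate_structural(g$tracts, cfg)
  d <- compute_mortgage_discrimination(s$mortgage$loans_minority,
                                       s$mortgage$loans_total,
                                       s$mortgage$households_minority,
                                       s$mortgage$households_total)
  n_red <- length(d)
  expect_gt(n_red, 400)
  expect_lt(abs(sum(d < 1) - 0.5 * n_red), 3 * sqrt(n_red * 0.25))
})

test_that("ground truth round-trips through JSON unchanged", {
  g <- shared_geo()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$ground_truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$beta_transport, g$ground_truth$beta_transport)
  expect_equal(back$beta_occupation, g$ground_truth$beta_occupation)
  expect_equal(back$true_q5_logodds, g$ground_truth$true_q5_logodds,
               tolerance = 1e-12)
  expect_equal(back$tracts, g$ground_truth$tracts, tolerance = 1e-12)
})

test_that("null world yields null Q5-vs-Q1 associations in >=90% of replicates", {
  covered <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(n_metro_areas = 5, tracts_per_metro = 200,
                            nonmetro_tracts = 500, beta_transport = 0,
                            beta_occupation = 0, seed = 1000L + r)
    g <- generate_geography(cfg)
    gt <- g$ground_truth$tracts
    # flags from the analytic expected prevalences (no Monte Carlo needed
    # for a null-recovery check of the regression stage)
    wprev <- make_prevalence(gt$tract_id, gt$expected_workplace_prev)
    tprev <- make_prevalence(gt$tract_id, gt$expected_transport_prev,
                             "transportation")
    flags <- classify_cumulative_high(wprev, tprev)
    quin <- tract_quintiles(g$tracts, "minority", quiet = TRUE)
    de <- build_design(g$tracts, quin, model_spec("logistic", "minority"),
                       flags = flags)
    fit <- suppressWarnings(fit_cumulative_logistic(de))
    e <- q5_effect(fit)
    if (is.finite(e$ci_low) && e$ci_low <= 1 && e$ci_high >= 1)
      covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})
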