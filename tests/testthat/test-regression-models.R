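# Shared design built from the cached geography and its analytic
# expected prevalences (no Monte Carlo needed for model-contract tests).
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- shared_geo()
      gt <- g$ground_truth$tracts
      wp <- make_prevalence(gt$tract_id, gt$expected_workplace_prev)
      tp <- make_prevalence(gt$tract_id, gt$expected_transport_prev,
                            "transportation")
      quin <- tract_quintiles(g$tracts, "minority", quiet = TRUE)
      flags <- classify_cumulative_high(wp, tp)
      cache <<- list(g = g, wp = wp, tp = tp, quin = quin, flags = flags)
    }
    cache
  }
})

test_that("design dimensions honor the stated degrees of freedom", {
  fx <- model_fixture()
  de <- build_design(fx$g$tracts, fx$quin, model_spec("logistic", "minority"),
                     flags = fx$flags)
  expect_identical(sum(grepl("^dens", names(de$data))), 8L)
  expect_identical(sum(grepl("^tensor", names(de$data))), 20L)
  expect_s3_class(de$data$q_minority, "factor")
  # design construction is deterministic and seed-free
  de2 <- build_design(fx$g$tracts, fx$quin, model_spec("logistic", "minority"),
                      flags = fx$flags)
  expect_identical(de$data, de2$data)
})

test_that("Poisson outcome rounding and offset follow the contract", {
  fx <- model_fixture()
  tr <- fx$g$tracts
  tr$workers <- 1000L
  wp1 <- make_prevalence(tr$tract_id, 0.147)
  de <- build_design(tr, fx$quin, model_spec("poisson", "minority",
                                             offset = "workers"),
                     prevalence = wp1)
  expect_true(all(de$data$y == 147))
  expect_equal(de$data$off, rep(log(1000), nrow(de$data)), tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the aliased columns named", {
  fx <- model_fixture()
  tr <- fx$g$tracts
  tr$pct_low_income <- tr$pct_unemployed  # perfectly collinear covariates
  expect_error(build_design(tr, fx$quin,
                            model_spec("logistic", "minority",
                                       ses_adjusted = TRUE),
                            flags = fx$flags),
               "rank deficient.*pct_low_income")
})

test_that("model_spec enforces family invariants", {
  expect_error(model_spec("poisson", offset = "none"),
               class = "noisequity_config_error")
  expect_error(model_spec("linear"), class = "noisequity_config_error")
})

test_that("logistic fit: duplication invariance and Q1 reference", {
  fx <- model_fixture()
  de <- build_design(fx$g$tracts, fx$quin, model_spec("logistic", "minority"),
                     flags = fx$flags)
  m <- suppressWarnings(fit_cumulative_logistic(de))
  expect_identical(m$effects$estimate[m$effects$quintile == 1], 1)
  # duplicating every row leaves the point OR unchanged
  de_dup <- de
  de_dup$data <- rbind(de$data, de$data)
  de_dup$n <- nrow(de_dup$data)
  m_dup <- suppressWarnings(fit_cumulative_logistic(de_dup))
  expect_equal(q5_effect(m_dup)$estimate, q5_effect(m)$estimate,
               tolerance = 1e-6)
})

test_that("Poisson fit: offset contract under denominator doubling", {
  fx <- model_fixture()
  de <- build_design(fx$g$tracts, fx$quin,
                     model_spec("poisson", "minority", offset = "workers"),
                     prevalence = fx$wp)
  m <- fit_prevalence_poisson(de)
  de2 <- de
  de2$data$y <- 2 * de2$data$y
  de2$data$off <- de2$data$off + log(2)
  m2 <- fit_prevalence_poisson(de2)
  expect_equal(q5_effect(m2)$estimate, q5_effect(m)$estimate,
               tolerance = 1e-8)
})

test_that("relabeling the reference quintile inverts the ratio", {
  fx <- model_fixture()
  de <- build_design(fx$g$tracts, fx$quin,
                     model_spec("poisson", "minority", offset = "workers"),
                     prevalence = fx$wp)
  m <- fit_prevalence_poisson(de)
  de_rev <- de
  de_rev$data$q_minority <- factor(de_rev$data$q_minority,
                                   levels = c(5, 2, 3, 4, 1))
  fit_rev <- glm(de_rev$formula, data = de_rev$data, family = poisson(),
                 offset = off)
  or_15 <- exp(coef(fit_rev)[["q_minority1"]])
  expect_equal(or_15, 1 / q5_effect(m)$estimate, tolerance = 1e-6)
})

test_that("injected quintile effects are recovered within the Wald CI", {
  fx <- model_fixture()
  de_l <- build_design(fx$g$tracts, fx$quin, model_spec("logistic", "minority"),
                       flags = fx$flags)
  sim <- simulate_quintile_outcome(de_l, beta_q = 1.0, baseline = -2,
                                   seed = 61L)
  m <- suppressWarnings(fit_cumulative_logistic(sim))
  e <- q5_effect(m)
  expect_true(e$ci_low <= exp(1.0) && exp(1.0) <= e$ci_high)

  de_p <- build_design(fx$g$tracts, fx$quin,
                       model_spec("poisson", "minority", offset = "workers"),
                       prevalence = fx$wp)
  sim_p <- simulate_quintile_outcome(de_p, beta_q = 0.2, baseline = log(0.1),
                                     seed = 62L)
  m_p <- fit_prevalence_poisson(sim_p)
  e_p <- q5_effect(m_p)
  expect_true(e_p$ci_low <= exp(0.2) && exp(0.2) <= e_p$ci_high)
})

test_that("redlining linear model: invariances and slope recovery", {
  fx <- model_fixture()
  g <- fx$g
  cfg <- generator_config(n_metro_areas = 3, tracts_per_metro = 50,
                          nonmetro_tracts = 50, blocks_per_tract = c(6L, 14L),
                          redline_fraction = 0.9, seed = 42L)
  s <- generate_structural(g$tracts, cfg)
  idx <- structural_indices(s$holc, s$mortgage)

  # outcome independent of hrs: 1-to-4 effect CI covers 0
  set.seed(63)
  wp0 <- make_prevalence(g$tracts$tract_id, runif(nrow(g$tracts), 0.1, 0.2))
  tp0 <- make_prevalence(g$tracts$tract_id, runif(nrow(g$tracts), 0.1, 0.2),
                         "transportation")
  m0 <- suppressWarnings(fit_redlining_linear(g$tracts, idx, wp0, tp0,
                                              "sustained"))
  expect_true(m0$effects$ci_low <= 0 && 0 <= m0$effects$ci_high)

  # location invariance: adding a constant to the outcome moves nothing
  wp_shift <- wp0; wp_shift$omega <- wp_shift$omega + 0.05
  tp_shift <- tp0; tp_shift$omega <- tp_shift$omega + 0.05
  m_shift <- suppressWarnings(fit_redlining_linear(g$tracts, idx, wp_shift,
                                                   tp_shift, "sustained"))
  expect_equal(m_shift$effects$estimate, m0$effects$estimate,
               tolerance = 1e-8)

  # injected slope 0.005 per HRS unit -> 1.5 percentage points per 1-to-4
  hrs_all <- idx$hrs[match(g$tracts$tract_id, idx$tract_id)]
  set.seed(64)
  base <- runif(nrow(g$tracts), 0.1, 0.2)
  omega_inj <- base + 0.005 * ifelse(is.na(hrs_all), 0, hrs_all) +
    rnorm(nrow(g$tracts), 0, 0.004)
  wp1 <- make_prevalence(g$tracts$tract_id, omega_inj)
  tp1 <- make_prevalence(g$tracts$tract_id, omega_inj, "transportation")
  m1 <- suppressWarnings(fit_redlining_linear(g$tracts, idx, wp1, tp1,
                                              "sustained"))
  expect_true(m1$effects$ci_low <= 1.5 && 1.5 <= m1$effects$ci_high)
})

test_that("SES sensitivity nests the main model", {
  fx <- model_fixture()
  de <- build_design(fx$g$tracts, fx$quin,
                     model_spec("poisson", "minority", offset = "workers"),
                     prevalence = fx$wp)
  sens <- fit_sensitivity(de)
  # adding covariates never reduces the maximized log-likelihood
  expect_gte(sens$ses$loglik + 1e-6, sens$main$loglik)
  expect_identical(nrow(sens$comparison), 5L)

  # constant SES columns alias the intercept and leave estimates unchanged
  de_const <- de
  de_const$data$pct_low_income <- 0.25
  de_const$data$pct_no_diploma <- 0.12
  main <- fit_prevalence_poisson(de_const)
  spec2 <- de_const$spec; spec2$ses_adjusted <- TRUE
  de2 <- de_const; de2$spec <- spec2
  de2$formula <- as.formula(paste("y ~ q_minority +",
                                  paste(c("pct_unemployed", "urban",
                                          paste0("dens", 1:8),
                                          paste0("tensor", 1:20),
                                          "pct_low_income", "pct_no_diploma"),
                                        collapse = " + ")))
  m2 <- fit_prevalence_poisson(de2)
  expect_equal(q5_effect(m2)$estimate, q5_effect(main)$estimate,
               tolerance = 1e-8)
})
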