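#' Simulate an outcome with injected quintile effects
#'
#' Parameter-recovery harness: replaces the outcome of a built design
#' with one simulated from a known generalized linear model in which
#' the quintile indicators carry the injected log-scale effects and all
#' other covariates have zero coefficients. Logistic designs get
#' Bernoulli outcomes with `logit(p) = baseline + beta[q]`; Poisson
#' designs get counts with `log(mu) = offset + baseline + beta[q]`.
#' Used by the recovery suites to check that the fitted Q5-vs-Q1
#' confidence interval covers the injected truth.
#'
#' @param design A [build_design()] for a single-exposure model.
#' @param beta_q Named or length-4 numeric vector of log-scale effects
#'   for quintiles 2-5 (Q1 is the reference). A scalar is taken as the
#'   Q5 effect with zero for Q2-Q4.
#' @param baseline Log-scale intercept (logit of the Q1 outcome
#'   probability, or log of the Q1 rate).
#' @param seed Seed.
#' @return The design with its outcome column replaced.
#' @export
simulate_quintile_outcome <- function(design, beta_q, baseline, seed = 1L) {
  stopifnot(inherits(design, "noisequity_design"),
            length(design$spec$exposure) == 1L)
  if (length(beta_q) == 1L) beta_q <- c(0, 0, 0, beta_q)
  stopifnot(length(beta_q) == 4L)
  q <- as.integer(as.character(design$data[[paste0("q_",
                                                   design$spec$exposure)]]))
  lp <- baseline + c(0, beta_q)[q]
  set.seed(substream_seed(seed, "recovery"))
  d <- design$data
  if (design$spec$family == "logistic") {
    d$y <- stats::rbinom(length(lp), 1, stats::plogis(lp))
  } else {
    d$y <- stats::rpois(length(lp), exp(d$off + lp))
  }
  design$data <- d
  design
}

#' Extract the Q5-vs-Q1 effect of a fitted model
#'
#' @param model A `noisequity_model` from one of the quintile fits.
#' @param exposure Which exposure's effects to read.
#' @return One effects row (quintile 5).
#' @export
q5_effect <- function(model, exposure = model$spec$exposure[1]) {
  e <- model$effects
  e[e$exposure == exposure & e$quintile == 5L, , drop = FALSE]
}
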