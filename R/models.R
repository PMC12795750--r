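#' Specification of one regression stage
#'
#' Describes one of the model families linking racial/ethnic composition
#' (as stratum-specific quintiles) or the historical redlining score to
#' noise-pollution outcomes: logistic for the cumulative-high flag,
#' Poisson with a log-denominator offset for each source's exposed
#' count, and linear for the redlining analysis stratified by sustained
#' mortgage discrimination. All families adjust for percent unemployed,
#' urbanicity (except the all-urban redlining model), a natural spline
#' of log population density with 8 degrees of freedom, and a 4 x 5
#' tensor-product B-spline smooth of the tract centroid
#' latitude/longitude with 20 total basis functions.
#'
#' @param family `"logistic"`, `"poisson"` or `"linear"`.
#' @param exposure `"minority"` (combined) or a character vector of
#'   racial/ethnic subgroup quintile variables.
#' @param offset `"none"`, `"workers"` or `"residents"`; required for
#'   the Poisson family.
#' @param ses_adjusted Add the two socioeconomic sensitivity covariates
#'   (percent low income, percent without a high-school diploma).
#' @param stratum For the linear family: `"sustained"` or
#'   `"not_sustained"`.
#' @return A list of class `noisequity_model_spec`.
#' @export
model_spec <- function(family = c("logistic", "poisson", "linear"),
                       exposure = "minority",
                       offset = c("none", "workers", "residents"),
                       ses_adjusted = FALSE, stratum = NULL) {
  family <- match.arg(family)
  offset <- match.arg(offset)
  if (family == "poisson" && offset == "none")
    stop_config("the Poisson family requires an offset (workers or residents)")
  if (family == "linear" && is.null(stratum))
    stop_config("the linear family requires a stratum (sustained / not_sustained)")
  structure(list(family = family, exposure = exposure, offset = offset,
                 ses_adjusted = ses_adjusted, stratum = stratum),
            class = "noisequity_model_spec")
}

# Spatial/compositional covariate basis shared by every model family:
# 8-df natural spline of log density plus a 4 x 5 tensor-product
# B-spline over latitude/longitude (20 columns).
covariate_basis <- function(tracts, include_urban = TRUE) {
  dens <- splines::ns(log(tracts$pop_density), df = 8)
  colnames(dens) <- paste0("dens", 1:8)
  blat <- splines::bs(tracts$centroid_lat, df = 4)
  blon <- splines::bs(tracts$centroid_lon, df = 5)
  tens <- matrix(NA_real_, nrow(tracts), 20)
  k <- 0L
  for (i in 1:4) for (j in 1:5) {
    k <- k + 1L
    tens[, k] <- blat[, i] * blon[, j]
  }
  colnames(tens) <- paste0("tensor", 1:20)
  out <- data.frame(pct_unemployed = tracts$pct_unemployed, dens, tens,
                    pct_low_income = tracts$pct_low_income,
                    pct_no_diploma = tracts$pct_no_diploma)
  if (include_urban) out$urban <- as.integer(tracts$ruca_code <= 3)
  out
}

covariate_terms <- function(include_urban = TRUE, ses_adjusted = FALSE) {
  terms <- c("pct_unemployed", if (include_urban) "urban",
             paste0("dens", 1:8), paste0("tensor", 1:20))
  if (ses_adjusted) terms <- c(terms, "pct_low_income", "pct_no_diploma")
  terms
}

#' Build the design for a quintile-exposure model
#'
#' Assembles outcome, offset, quintile exposure factors and the
#' covariate basis into one model frame, dropping tracts with excluded
#' prevalence or missing covariates, and errors on a rank-deficient
#' design naming the aliased columns. For the Poisson family the
#' outcome is `round(omega * denominator)` with offset
#' `log(denominator)`.
#'
#' @param tracts Tract table.
#' @param quintiles One `QuintileAssignment` table (combined minority)
#'   or a named list of them (subgroup exposures).
#' @param spec A [model_spec()].
#' @param flags `CumulativeFlag` table (logistic family).
#' @param prevalence `PrevalenceEstimate` table (Poisson family).
#' @return A list of class `noisequity_design`: `data` (model frame),
#'   `formula`, `spec`, `n`.
#' @export
build_design <- function(tracts, quintiles, spec, flags = NULL,
                         prevalence = NULL) {
  stopifnot(inherits(spec, "noisequity_model_spec"))
  if (is.data.frame(quintiles)) quintiles <- list(minority = quintiles)
  d <- data.frame(tract_id = tracts$tract_id, stringsAsFactors = FALSE)
  d <- cbind(d, covariate_basis(tracts, include_urban = TRUE))
  qvars <- character(0)
  for (nm in names(quintiles)) {
    qt <- quintiles[[nm]]
    v <- paste0("q_", nm)
    d[[v]] <- factor(qt$quintile[match(d$tract_id, qt$tract_id)], levels = 1:5)
    qvars <- c(qvars, v)
  }
  denom_col <- switch(spec$offset, workers = "workers",
                      residents = "population", none = NULL)
  if (spec$family == "logistic") {
    if (is.null(flags)) stop("logistic family needs the cumulative-high flags")
    d$y <- as.integer(flags$high_both[match(d$tract_id, flags$tract_id)])
    d$off <- 0
  } else if (spec$family == "poisson") {
    if (is.null(prevalence)) stop("poisson family needs a prevalence table")
    p <- prevalence[!prevalence$excluded & !is.na(prevalence$omega), ]
    om <- p$omega[match(d$tract_id, p$tract_id)]
    denom <- tracts[[denom_col]]
    d$y <- round(om * denom)
    d$off <- ifelse(denom > 0, log(denom), NA_real_)
  } else {
    stop("use fit_redlining_linear() for the linear family")
  }
  keep <- stats::complete.cases(d)
  d <- droplevels(d[keep, , drop = FALSE])
  if (any(d$y < 0)) stop("negative outcome counts")
  if (spec$family == "poisson" && all(d$y == 0))
    stop("all outcome counts are zero; nothing to fit")
  rhs <- c(qvars, covariate_terms(TRUE, spec$ses_adjusted))
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  check_design_rank(d, fml)
  structure(list(data = d, formula = fml, spec = spec, n = nrow(d)),
            class = "noisequity_design")
}

check_design_rank <- function(d, fml) {
  mm <- stats::model.matrix(fml, d)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop(sprintf("design matrix is rank deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")))
  }
  invisible(TRUE)
}

fit_glm_design <- function(design, family) {
  # the formula carries no s() terms, so mgcv solves the identical
  # unpenalized likelihood; its PIRLS is markedly more stable than
  # glm.fit when the rich spatial basis quasi-separates sparse strata
  # (stats::glm can return astronomically diverged coefficients while
  # reporting convergence on these designs)
  fit <- suppressWarnings(mgcv::gam(design$formula, data = design$data,
                                    family = family, offset = off))
  ct <- coef_table(fit)
  expo <- grepl(paste0("^q_(", paste(design$spec$exposure, collapse = "|"),
                       ")"), rownames(ct))
  sep <- any(abs(ct[expo, 1]) > 15 | ct[expo, 2] > 15)
  list(fit = fit, separation = isTRUE(sep))
}

coef_table <- function(fit) {
  if (inherits(fit, "gam")) summary(fit)$p.table else
    summary(fit)$coefficients
}

quintile_effects <- function(fit, qvars, ratio = TRUE) {
  sm <- coef_table(fit)
  out <- list()
  for (v in qvars) {
    rows <- data.frame(exposure = sub("^q_", "", v), quintile = 1:5,
                       estimate = if (ratio) 1 else 0,
                       ci_low = NA_real_, ci_high = NA_real_,
                       stringsAsFactors = FALSE)
    for (q in 2:5) {
      term <- paste0(v, q)
      if (term %in% rownames(sm)) {
        b <- sm[term, 1]; se <- sm[term, 2]
        est <- c(b, b - 1.96 * se, b + 1.96 * se)
        if (ratio) est <- exp(est)
        rows[rows$quintile == q, c("estimate", "ci_low", "ci_high")] <- est
      }
    }
    out[[v]] <- rows
  }
  do.call(rbind, out)
}

model_result <- function(fit, design, effects, separation = FALSE) {
  structure(list(family = design$spec$family, effects = effects,
                 coefficients = coef_table(fit),
                 deviance = stats::deviance(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n = design$n, separation = separation, fit = fit,
                 spec = design$spec),
            class = "noisequity_model")
}

#' Fit the cumulative-high logistic model
#'
#' Logistic regression of the cumulative-high flag on quintile
#' exposures and the covariate basis; reports odds ratios per quintile
#' versus Q1 with Wald 95% CIs. Complete separation, if detected, is
#' flagged on the result rather than silently reported.
#'
#' @param design A logistic [build_design()].
#' @return A `noisequity_model` with an `effects` table of ORs.
#' @export
fit_cumulative_logistic <- function(design) {
  stopifnot(design$spec$family == "logistic")
  r <- fit_glm_design(design, stats::binomial())
  qvars <- paste0("q_", design$spec$exposure)
  eff <- quintile_effects(r$fit, qvars, ratio = TRUE)
  if (r$separation) warning("complete separation detected; estimates flagged")
  model_result(r$fit, design, eff, separation = r$separation)
}

#' Fit a prevalence Poisson model
#'
#' Poisson regression of the exposed count with a log-denominator
#' offset; reports prevalence ratios per quintile versus Q1 with Wald
#' 95% CIs.
#'
#' @param design A Poisson [build_design()].
#' @return A `noisequity_model` with an `effects` table of PRs.
#' @export
fit_prevalence_poisson <- function(design) {
  stopifnot(design$spec$family == "poisson")
  r <- fit_glm_design(design, stats::poisson())
  qvars <- paste0("q_", design$spec$exposure)
  eff <- quintile_effects(r$fit, qvars, ratio = TRUE)
  model_result(r$fit, design, eff, separation = r$separation)
}

#' Fit the redlining linear model within one discrimination stratum
#'
#' Linear regression of the average workplace/transportation exposure
#' prevalence `(omega_work + omega_trans)/2` on the historical
#' redlining score (entered continuously), restricted to tracts with a
#' defined HRS and to the requested sustained-discrimination stratum.
#' Covariates are percent unemployed, the 8-df density spline and the
#' 20-df latitude/longitude tensor smooth; no urbanicity term because
#' every HOLC-graded tract is urban. The reported effect is `3 x` the
#' HRS coefficient expressed in percentage points — the change
#' associated with moving from 1 to 4 on the HRS scale.
#'
#' @param tracts Tract table.
#' @param indices `StructuralIndices` table (`hrs`, `sustained`).
#' @param workplace,transport `PrevalenceEstimate` tables.
#' @param stratum `"sustained"` or `"not_sustained"`.
#' @param ses_adjusted Add the SES sensitivity covariates.
#' @return A `noisequity_model`; `effects` holds the 1-to-4 HRS effect
#'   in percentage points with its Wald 95% CI.
#' @export
fit_redlining_linear <- function(tracts, indices, workplace, transport,
                                 stratum = c("sustained", "not_sustained"),
                                 ses_adjusted = FALSE) {
  stratum <- match.arg(stratum)
  w <- workplace[!workplace$excluded & !is.na(workplace$omega), ]
  t <- transport[!transport$excluded & !is.na(transport$omega), ]
  hrs <- indices$hrs[match(tracts$tract_id, indices$tract_id)]
  sus <- indices$sustained[match(tracts$tract_id, indices$tract_id)]
  y <- (w$omega[match(tracts$tract_id, w$tract_id)] +
          t$omega[match(tracts$tract_id, t$tract_id)]) / 2
  keep <- !is.na(hrs) & !is.na(sus) & !is.na(y) &
    (if (stratum == "sustained") sus else !sus)
  # spline knots are placed on the analysis subset (HOLC-graded tracts),
  # not the full national table
  sub <- tracts[keep, , drop = FALSE]
  d <- data.frame(tract_id = sub$tract_id, stringsAsFactors = FALSE)
  d <- cbind(d, covariate_basis(sub, include_urban = FALSE))
  d$hrs <- hrs[keep]
  d$y <- y[keep]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 50)
    warning(sprintf("stratum '%s' has only %d tracts; fit proceeds", stratum,
                    nrow(d)))
  rhs <- c("hrs", covariate_terms(FALSE, ses_adjusted))
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  check_design_rank(d, fml)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  b <- sm["hrs", 1]; se <- sm["hrs", 2]
  eff <- data.frame(exposure = "hrs", quintile = NA_integer_,
                    estimate = 300 * b, ci_low = 300 * (b - 1.96 * se),
                    ci_high = 300 * (b + 1.96 * se),
                    stringsAsFactors = FALSE)
  spec <- model_spec("linear", exposure = "hrs", stratum = stratum,
                     ses_adjusted = ses_adjusted)
  design <- structure(list(data = d, formula = fml, spec = spec,
                           n = nrow(d)), class = "noisequity_design")
  model_result(fit, design, eff)
}

#' SES sensitivity refit
#'
#' Refits a quintile-exposure design with the two socioeconomic
#' covariates added (percent low income, percent without a high-school
#' diploma) and pairs the quintile effects of the main and adjusted
#' fits.
#'
#' @param design A [build_design()] with `ses_adjusted = FALSE`.
#' @return A list with `main`, `ses` (both `noisequity_model`) and
#'   `comparison` (effects side by side).
#' @export
fit_sensitivity <- function(design) {
  stopifnot(inherits(design, "noisequity_design"),
            design$spec$family %in% c("logistic", "poisson"))
  fit_fun <- if (design$spec$family == "logistic") fit_cumulative_logistic
             else fit_prevalence_poisson
  main <- fit_fun(design)
  spec2 <- design$spec
  spec2$ses_adjusted <- TRUE
  rhs <- c(paste0("q_", spec2$exposure), covariate_terms(TRUE, TRUE))
  design2 <- design
  design2$spec <- spec2
  design2$formula <- stats::as.formula(paste("y ~",
                                             paste(rhs, collapse = " + ")))
  ses <- fit_fun(design2)
  comp <- merge(main$effects, ses$effects,
                by = c("exposure", "quintile"),
                suffixes = c("_main", "_ses"))
  list(main = main, ses = ses, comparison = comp)
}
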