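---
title: "Methods: cumulative noise-inequity analysis at the census-tract level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative noise-inequity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generator does and does not
emulate, the numerical choices, and the design decisions taken where
the design was genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The two exposure prevalences

### Workplace noise

For tract $i$ with employment counts $e_{ig}$ across the 22 major
occupational groups and a job-exposure matrix giving each group a
normal 8-h TWA distribution $N(\mu_g, \sigma_g^2)$ on the dBA scale,
the quantity of interest is the proportion of workers whose TWA
exceeds the NIOSH Recommended Exposure Limit of 85 dBA. Each Monte
Carlo iteration draws the number of exposed workers in group $g$ as
$\mathrm{Binomial}(e_{ig}, p_g)$ with
$p_g = 1 - \Phi((85 - \mu_g)/\sigma_g)$ — exactly the distribution of
thresholding one independent TWA draw per worker, but orders of
magnitude faster — and records the employment-weighted exposed
fraction. The reported $\omega_{w,i}$ is the 50th percentile over
iterations; the 95% interval is the 2.5th/97.5th percentiles. Tracts
with $\le 20$ workers are excluded (inclusive boundary, mirroring the
published exclusion rule).

*Assumptions.* Normality on the dBA scale (dBA is already
log-transformed sound energy, and the JEM arrives as mean/sd summary
parameters, so a normal is the maximum-entropy choice consistent with
the inputs); worker-level independence given the group; and a JEM that
covers every group with nonzero employment (a missing group is a hard
error naming the group, never a silent drop).

*A note on the interval.* The percentile interval over iterations
converges, as iterations grow, to the fixed 2.5–97.5 quantile spread
of the per-iteration distribution — it quantifies the sampling
variability of the exposed fraction, not Monte Carlo error, and its
width therefore stabilizes rather than shrinking with more iterations.
The suite checks that the large-iteration width sits at its analytic
normal-approximation value.

### Transportation noise

Block-level 24-h $L_{Aeq}$ levels are aggregated to the tract. Each
iteration perturbs every block level with independent
$N(0, \mathrm{sd}^2)$ noise (default 2 dBA), classes a block's entire
population as exposed when the perturbed level strictly exceeds 55 dBA
(the health-based all-transportation threshold; strict `>` matches the
published definition), and records the population-weighted exposed
fraction. Summaries are the same 50th/2.5th/97.5th percentiles; with
zero uncertainty the estimator reduces exactly to the deterministic
population fraction in blocks above threshold. Tracts with $\le 20$
residents are excluded.

*Design decisions.* The published national noise map provides block
levels without uncertainty, and the original work's exact Monte Carlo
protocol is not public; a configurable block-level perturbation is the
transparent stand-in, reproducing the "avoid overestimation near the
threshold" behavior while keeping `sd = 0` as the deterministic limit.
The block-binary rule (a block's whole population is exposed when its
level exceeds the threshold) was chosen over sub-block allocation,
which the source data cannot support. Road, rail and air are one
combined level by construction of the inputs.

### Aggregation

The exposed count at county/metro/nationwide level is
$\sum_i \mathrm{pop}_i\,\omega_i$ over non-excluded tracts, and the
percentage is $100 \times$ count / population. When per-iteration
draws are retained the CI (and the central count) use the percentiles
of the per-iteration *totals*: with many zero-inflated tracts the sum
of per-tract medians is not bracketed by the totals' percentiles, so
the central estimate follows the same 50th-percentile convention as
the interval. Without draws, the fallback is the delta method on
per-tract CI widths (tracts independent, SE = width/3.92); the
deterministic sum-of-medians identity (nationwide = sum of counties)
holds exactly in that fallback and approximately under the
median-of-totals rule.

## 2. Inequity metrics

The exposure-risk ratio for group $j$ is
$$\mathrm{ERR}_j = \frac{\sum_i \omega_i p_{ij} / \sum_i p_{ij}}
                        {\sum_i \omega_i t_{ij} / \sum_i t_{ij}},$$
the group's exposure-weighted population share relative to the total
population's. ERR > 1 means over-representation among the exposed.
The cumulative ERR substitutes $\omega_i := \omega_{w,i}\,
\omega_{t,i}$ (tracts missing either source are dropped pairwise).
CIs: resample whole tracts with replacement 100 times; report the
50th/2.5th/97.5th percentiles of the replicate ERRs. Tracts are the
resampling unit because the tract is the unit of observation
throughout.

A tract is *cumulatively high* when strictly above the 75th percentile
of both prevalence distributions, percentiles computed over
non-excluded tracts nationwide with linear interpolation between order
statistics (quantile type 7 — fixed explicitly for reproducibility;
the source publication does not state its interpolation rule).

Exposure quintiles are stratum-specific: each metropolitan area is its
own stratum and all nonmetropolitan tracts form one pooled stratum
(this is the default reading of "metropolitan/nonmetropolitan-specific
quintiles", accounting for city-to-city differences in composition; a
single pooled metropolitan stratum is available via
`quintile_mode = "pooled"`). Boundaries are the stratum's 20/40/60/80th
percentiles; bins are right-closed so ties share a quintile and an
all-equal stratum collapses to quintile 1; strata with fewer than five
tracts are binned by the same rank rule with a warning.

## 3. Structural-racism indices

The historical redlining score renormalizes by the graded area,
$\mathrm{HRS} = (1A + 2B + 3C + 4D)/(A{+}B{+}C{+}D)$, keeping the
score in $[1, 4]$, and is defined only when at least 20% of the tract
overlaps HOLC-graded neighborhoods (inclusive boundary). Whether the
published score renormalizes or gives ungraded area neutral weight is
not fully specified; renormalization is adopted and flagged here. The
mortgage-discrimination index is
$D = (L_{min}/L)/(H_{min}/H)$ with loans pooled over 1990–2000 and
households from the 2000 census; $D < 1$ (strict) classifies sustained
discrimination, and $D$ is undefined when $L$, $H$ or $H_{min}$ is
zero.

## 4. Regression stages

Three families, all with the same covariate basis: percent unemployed,
an urbanicity indicator (RUCA 1–3), a natural spline of log population
density with 8 degrees of freedom (knots at equispaced quantiles;
density is logged first because of its heavy right skew — a documented
choice the source does not specify), and a tensor-product smooth of
the tract centroid with 20 total basis functions, built as the
columnwise products of 4 latitude × 5 longitude B-spline bases.
"Twenty degrees of freedom" was read as 20 total basis functions (not
20 per margin); the 4 × 5 marginal split is unstated anywhere and
documented here. The smooths are *unpenalized* regression-spline bases
inside ordinary GLMs: the degrees of freedom are fixed a priori, so
penalized estimation would introduce smoothing parameters the analysis
does not define.

- **Logistic**: cumulative-high flag on quintile indicators (Q2–Q5 vs
  Q1); odds ratios with Wald 95% CIs.
- **Poisson**: exposed count `round(omega * denominator)` with offset
  `log(denominator)` (workers for workplace, residents for
  transportation); prevalence ratios with Wald CIs. Rounding is needed
  because the prevalence pipeline yields proportions while the model
  is a count model.
- **Linear** (redlining): outcome is the average of the two
  prevalences, restricted to HOLC-graded tracts and stratified by
  sustained discrimination; HRS enters continuously (assumed; the
  source does not say whether it was categorical); no urbanicity term
  because every HOLC tract is urban; spline knots are placed on the
  analysis subset, not the national table. The reported effect is 3 ×
  the HRS coefficient × 100 — percentage points per 1-to-4 change.
- **SES sensitivity**: the same fit with percent low-income and
  percent without a high-school diploma added; these are potential
  mediators, so they are sensitivity covariates rather than main-model
  confounders.

*Fitting.* The formulas contain no penalized terms, so `stats::glm`
and `mgcv::gam` solve the identical likelihood; `gam` is used because
its iteration is markedly more stable on desk-scale designs where the
rich spatial basis quasi-separates sparse strata (`glm.fit` can return
astronomically diverged coefficients while reporting convergence).
Complete or quasi-complete separation is detected from diverged
exposure coefficients (|coef| or SE above 15 on the log scale) and
flagged on the result — estimates are reported, never silently
repaired. Wald CIs are used throughout, matching standard OR/PR
reporting.

## 5. The synthetic world

The generator emulates the statistical structure of the real inputs so
the pipeline can be validated end-to-end with known truth:

- **Geography**: configurable metro areas, each a jittered grid of
  tracts, plus a scattered nonmetropolitan stratum (RUCA 1–3 vs 4–10).
- **Composition**: minority proportion is a smooth logit-scale field
  within each metro (Gaussian kernel around a random urban core,
  amplitude `minority_cluster_strength`, default 1.5 — strong enough
  to produce the within-metro segregation the quintile analyses
  exploit); the minority share splits into the five subgroups by a
  jittered Dirichlet; counts are multinomial so groups partition the
  tract population exactly. Nonmetro minority shares are drawn from
  the same marginal distribution as the metro base so urbanicity and
  composition are independent under the null configuration.
- **Workplace sorting**: employment across the 22 major groups is
  multinomial with the log-odds of the six conventionally noisy trades
  shifted by `beta_occupation` × minority proportion (default 1).
- **Block noise**: block $L_{Aeq}$ is normal (sd 3 dBA) around a tract
  mean of 47 dBA + 3.5 dBA urban bump + `beta_transport` × minority
  proportion (default 5 dBA per unit proportion) + 1.5 dBA tract
  noise. These constants were fixed once so that a default world shows
  roughly 15–20% urban transport exposure, ~2% nonmetro exposure and a
  ~14–17% workplace prevalence — the orders of magnitude reported for
  the US — and are not tuned thereafter.
- **Structural tables**: a `redline_fraction` of urban tracts receives
  HOLC overlaps sampled preferentially at high minority share, with
  the D-grade share increasing in minority proportion and ~8% of
  covered tracts kept below the 20% floor to exercise the missingness
  rule; mortgage counts are constructed so designated tracts have a
  *computed* D strictly below 1 and the rest sit at D ≈ 1 from above.
- **Ground truth** records the configured effects, each tract's
  analytic expected prevalences, and the implied crude Q5-vs-Q1 log
  odds; it is written next to the tables and never read by any
  analysis stage.
- **Seeding**: one master seed; each table draws from its own
  deterministically derived sub-stream, so identical config + seed
  reproduce byte-identical tables.

What the generator does **not** emulate: real TIGER geometry, ACS
sampling error and margins of error, the hierarchical-Bayesian
uncertainty structure of the real JEM, source-specific (road/rail/air)
noise surfaces, or the historical processes behind HOLC boundaries. A
green test therefore establishes that the estimators and models
recover what this stated world contains — not that desk-scale runs
reproduce published national estimates, which depend on ~72k tracts of
restricted-scale data.

## 6. Numerical choices and degenerate inputs

- All percentiles: quantile type 7.
- Exclusions are inclusive at the boundary (≤ 20 workers/residents);
  excluded tracts carry a reason and an absent omega, and drop
  pairwise from ERRs, percentile ranks and model designs.
- Zero-population tracts in the transport stage are excluded with
  their own reason rather than erroring.
- ERR with zero denominator prevalence is missing, not an error;
  bootstrap replicates whose ERR is undefined are dropped with a
  warning (all-undefined returns a missing result).
- Rank-deficient model designs are a hard error listing the aliased
  columns.
- The config hash is the md5 of the canonical JSON serialization of
  the run configuration (base R `tools::md5sum`).

## 7. Known limitations

Desk-scale geographies cannot support the cumulative-high logistic
model when events concentrate in one quintile — the fit is then
flagged as separated rather than reported as a finite estimate. The
per-iteration percentile interval is a variability band, not a Monte
Carlo standard error. The ecological caveats of the original design
carry over: tract-level associations, no individual co-exposure, and
exposure (not dose).
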