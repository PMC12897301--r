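---
title: "Modelling childhood cancer survival trends from registry case data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood cancer survival trends from registry case data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registrend)
```

## The problem

Hospital- and population-based childhood cancer registries monitor progress
in care by estimating overall survival (OS) and its evolution over calendar
time. Individual case records carry a diagnosis date, an age group at
diagnosis (`<1`, `1-4`, `5-9`, `10-14` years), a diagnostic classification
(ICCC group/subgroup), tumour behaviour, and a follow-up outcome. Three
methodological ingredients make trend reporting from such data non-trivial:

1. recent diagnosis cohorts have incomplete follow-up, so naive cohort
   estimates lag years behind the present;
2. the age composition of registered cases shifts over decades, confounding
   crude comparisons across periods;
3. "is survival improving, and did the pace change?" needs a model of the
   calendar-time effect with data-driven change points and honest
   uncertainty for the trend summary.

`registrend` implements the full stack: cohort Kaplan–Meier estimation, the
period approach for recent windows, case-pool age standardisation with
pooling/suppression rules, age-stratified Cox models with a piecewise-linear
calendar-year effect whose joinpoints are selected by BIC, model-based
age-standardised 5-year survival series, and the average absolute change in
survival (AACS) with a case-resampling bootstrap. Because real registry
records are confidential, the package ships a synthetic registry generator
with closed-form ground truth so that every stage is testable.

## Survival estimation

**Cohort Kaplan–Meier.** `kaplan_meier()` computes the product-limit
estimate truncated at a horizon (5 years by default), with Greenwood
variance. Ties follow the standard convention that deaths precede
censorings at equal times. 95% confidence intervals use the
log(−log S) (complementary log-log) transformation — the usual registry
choice, which keeps bounds inside [0, 1]; published registry reports rarely
state their CI scale, so this is a package decision, and the interval scale
is the only quantity affected by it. Survival time is computed from dates
as days/365.25; same-day outcomes are set to half a day so no zero-length
interval enters a risk set.

**Period approach.** For a recent calendar window (say 2019–2022),
`period_survival()` uses only the survival experience observed *inside* the
window: each case enters the risk set at `max(0, window start − diagnosis)`
years since diagnosis (delayed entry) and exits at the earliest of its
follow-up end, the window end and the horizon, with deaths counted only
inside the window. The product-limit estimator over these left-truncated
observations conditions each factor on being under observation, giving an
up-to-date estimate before any recent cohort completes follow-up. Cases
diagnosed in the final window year are excluded (they contribute no
follow-up yet) while that year still closes the window — so a 2019–2022
window draws on diagnoses from 2014–2021. Person-time is clipped at day
resolution from the actual dates, not whole years. When the window covers
all observed follow-up the estimator reduces exactly to the cohort
Kaplan–Meier, a property asserted in the test suite. In a context of
continuously improving care, period estimates still slightly underestimate
the survival of the most recent diagnosis year; the simulation tests verify
this ordering (above the last complete cohort, below current-year truth, on
average).

**Group comparisons** use the standard k-sample log-rank test
(`logrank_test()`), and `risk_reduction()` converts two survival
percentages into the relative reduction in 5-year risk of death,
`100 (1 − (100 − s_late)/(100 − s_early))`.

## Age standardisation

Registries standardise survival to their *own case pool*: the weight of age
group $a$ is its share of all cases registered for that tumour over the full
registration period (`derive_weights()`). Standardised estimates therefore
read on the scale of observed all-ages survival — unlike external-standard
weights — and
$\hat S_\mathrm{std} = \sum_a w_a \hat S_a$, with standard error
$\sqrt{\sum_a w_a^2\,\mathrm{se}_a^2}$ under independence of the age strata.
Independence is exact for stratum-specific Kaplan–Meier estimates (disjoint
cases) and an approximation for model-based estimates that share
coefficients; for the fitted trend series the package instead uses the full
joint delta method described below.

Small strata are handled by two registry rules, both implemented in
`pool_age_groups()` and `suppress_small()`:

* **Pooling.** Standardisation starts from three groups {0–4, 5–9, 10–14};
  the infant group is split out (for age-specific reporting tables) only
  when both `<1` and `1–4` hold at least 15 cases in every cohort. If any
  group in any cohort falls below 15 cases, adjacent groups are merged to
  {0–9, 10–14} for tumours typically diagnosed at older ages or {0–4, 5–14}
  for young-heavy tumours. The merge direction is a per-tumour hint because
  no general rule covers both cases; with no hint the package merges toward
  the neighbour yielding the larger combined count. If a two-group split is
  still deficient, everything collapses to 0–14 and the crude estimate is
  reported (no standardisation). Pooling is monotone: a higher case
  threshold never yields a finer grouping.
* **Suppression.** Estimates based on fewer than 15 cases are withheld;
  the boundary is strict (exactly 15 is reported). Rendered tables show
  suppressed cells as `-`, and the underlying estimate is never written to
  any output artifact.

Tumours whose incidence is concentrated in a narrow age range
(retinoblastoma, hepatoblastoma, extracranial/extragonadal germ cell
tumours, thyroid carcinoma) are exempted from standardisation via a
per-tumour flag (`tumour_group(standardise = FALSE)`).

## The Cox–joinpoint trend model

Let $y$ be the diagnosis year and $y_0$ the series start. The hazard of
death within 5 years of diagnosis for a case in age stratum $a$ is

$$ h_a(t \mid y) = h_{0a}(t)\, \exp\!\big(\beta_0 (y - y_0) +
   \textstyle\sum_k \beta_k \,(y - \tau_k)_+ \big), $$

an age-stratified Cox model whose log hazard is continuous and
piecewise-linear in calendar year, with hinges at the joinpoints $\tau_k$.
Coefficients are slope *increments*, so the slope of segment $k$ is
$\sum_{j \le k} \beta_j$ and continuity at each joinpoint is automatic.
Follow-up is right-truncated at 5 years (later deaths become censorings at
the horizon): the model targets 5-year survival, and truncation keeps the
at-risk experience comparable across the series.

**Fitting.** The stratified partial likelihood uses the Efron tie
correction (registry follow-up times are date-resolved but ties still
occur) and is maximised by Newton–Raphson with step halving to a gradient
norm of $10^{-8}$; the basis is internally mean-centred for conditioning
(the partial likelihood is invariant; baseline sums are un-centred
afterwards). The coefficient covariance is the inverse observed
information. Baseline cumulative hazards per stratum, $\Lambda_{0a}(t)$,
use the Breslow estimator evaluated at covariate 0, i.e. at the reference
year. The gradient/information kernel is a small C++ routine; fits match an
independent reference implementation to $10^{-6}$ on shared data, and the
partial likelihood matches exhaustive enumeration on tiny fixtures.

**Joinpoint selection.** Candidate joinpoints lie on integer calendar
years, every segment (including before the first and after the last
joinpoint) must span at least 3 years, and up to 2 joinpoints are
considered. The search is an exhaustive grid over all admissible
placements; the model minimising
$\mathrm{BIC} = -2\log\mathrm{PL} + p\,\log d$ wins, where $p$ counts the
basis coefficients and $d$ the number of events — the standard effective
sample size for Cox-model BIC. Joinpoint locations are not counted as
parameters by default (`bic(count_joinpoints = TRUE)` toggles this);
with the event-based penalty and location counting off, selection already
behaves conservatively in the no-trend simulations, and the paperless
convention keeps nested comparisons simple. Ties break toward fewer
joinpoints, then earlier years.

**Fitted series.** For each year, fitted stratum survival is
$\hat S_a(5 \mid y) = \exp(-\hat\Lambda_{0a}(5)\, e^{x(y)'\hat\beta})$ and
the age-standardised series applies the case-pool weights. Years beyond
the last fitted diagnosis year continue the last segment's slope and are
flagged as extrapolated — the series runs to the follow-up closure year
(e.g. fitted on 1999–2021 diagnoses, predicted through 2022). The 95% band
treats $(\hat\beta, \hat\Lambda_{01..0A})$ as jointly asymptotically normal:
$\mathrm{var}(\hat\Lambda_{0a}) = \sum_t d_t/S_{0}(t)^2 + q_a' V q_a$ with
$q_a = \sum_t d_t S_1(t)/S_0(t)^2$ and $V$ the coefficient covariance;
$\mathrm{cov}(\hat\Lambda_{0a}, \hat\beta) = -V q_a$, and strata covary
only through $\hat\beta$. The band is computed by the delta method on the
weighted sum and clipped to [0, 1]. A bootstrap band is available as a
cross-check through the bootstrap machinery.

**AACS.** The average absolute change in survival is
$(\hat S_\mathrm{std}(y_\mathrm{last}) - \hat S_\mathrm{std}(y_\mathrm{first}))
\times 100 / (y_\mathrm{last} - y_\mathrm{first})$, in percentage points
per year; `aacs(series, from, to)` also evaluates it per segment. The
headline statistic is the full-series value. Its confidence interval comes
from resampling cases with replacement (`bootstrap_aacs()`): each replicate
refits the coefficients and baselines *with the joinpoint locations held
fixed at the selected basis* (selection is not repeated per replicate),
recomputes the standardised series and its AACS, and the reported value and
95% CI are the median and the 2.5th/97.5th percentiles of the bootstrap
distribution (500 replicates by default). The case-pool weights are treated
as a fixed standard and are not re-derived per replicate. Resampling is
unstratified by default (a stratified-by-age variant would be a one-line
change in the resampling index and was not needed at registry sample
sizes); replicates that fail to fit — typically a resample emptying a
stratum of events — are dropped and counted, and more than 10% failures is
an error.

## The synthetic registry generator

`trend_scenario()` + `generate_registry()` produce registry-like case
tables with known truth. Case counts per year and age group are Poisson;
diagnosis dates are uniform within the year (immaterial at year
resolution); death times follow a piecewise-exponential baseline per age
group multiplied by $e^{\beta f(y)}$ — the *same* piecewise-linear year
basis the fitting module uses, so the fitted model is well-specified by
default; loss to follow-up is an independent exponential process; and
everything is censored at an administrative closure date. The 5-year
truncation is deliberately an analysis step, not a generator step.
`true_s5()` and `true_aacs()` return the closed-form truth
($S_a(5\mid y) = \exp(-\Lambda_a(5) e^{\beta f(y)})$, checked against
quadrature in the tests) for parameter-recovery assertions.

Default parameters emulate a national paediatric series: 23 incidence years
(1999–2021) at roughly 890 expected cases/year (about 20,500 cases),
administrative closure on 31 December 2022, baseline all-ages 5-year
survival near 75% at the series start rising to about 85% by its end
(log-hazard slope −0.023/year), about 3% of cases lost to follow-up within
5 years (annual loss hazard 0.006), 55% males, 0.6% second primaries, and a
tumour mix whose marginals match published registry quality indicators
(≈89.5% microscopic verification, ≈2% unspecified codes, ≈11% infants,
≈33% non-malignant among CNS tumours). These defaults are the package's
study conditions; they were chosen from the published registry description,
not adjusted against test outcomes.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: registration-completeness drift (real
non-malignant CNS and epithelial series grew partly from better capture),
age-dependent tumour mixes, cure-fraction or non-proportional-hazards
structure, informative loss to follow-up, and abrupt additive survival
jumps (a hinge in the log hazard cannot represent a step change — a known
limitation of joinpoint trend models generally). A misspecification check
of that last kind is what the break-recovery simulations probe: the
generator can place a sharp slope change, and selection must find it.

## Numerical and design choices

* **Convergence:** Newton–Raphson to gradient norm ≤ 1e-8, at most 100
  iterations, with step halving; a singular information matrix or apparent
  monotone likelihood (|coefficient| > 50, i.e. separation in the year
  effect) is an error, not a silent result.
* **Degenerate inputs:** empty case tables, strata without events, windows
  without person-time, and zero-event BIC all raise informative errors.
  A perfect linear fit in the CNS-proportion trend test (zero residual
  variance) returns p = 1 for a flat line and p = 0 otherwise rather than
  NaN.
* **Tie-breaks:** joinpoint-grid ties break toward fewer joinpoints, then
  earlier years, making selection deterministic.
* **Reproducibility:** the generator and the bootstrap are deterministic
  under their seeds; `run_report()` writes a manifest with the seed and the
  MD5 of the input snapshot so every reported number traces to its inputs.
* **Problem sizes in the test suite** (the package's own choices for a
  desk-scale validation): break-recovery runs use full-size registries
  (~20,000 cases, 100 replicates; break at 2010 with log-hazard slopes 0
  and +0.08/year); no-trend specificity uses ~5,000-case registries;
  bootstrap-coverage runs use 200 registries of ~2,800 cases at 200
  bootstrap replicates. Coverage of the percentile interval is asserted in
  [90%, 98%] around the nominal 95%.

## Known limitations

* Absolute (all-cause) survival only: no relative/net survival and no
  event-free survival (registries of this kind do not systematically record
  relapse).
* The delta-method band is pointwise and asymptotic; for very sparse
  tumours the bootstrap interval is the more trustworthy of the two.
* BIC selection with at most two joinpoints cannot represent more complex
  trend shapes, and no inference is attached to the joinpoint location
  itself (no permutation test, by design — selection is BIC-only).
* Period estimates inherit the method's mild conservatism when care is
  improving continuously.
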