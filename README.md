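# registrend

Survival trends from childhood cancer registry data.

`registrend` is an R package for registry epidemiologists and
biostatisticians who report overall survival (OS) and its calendar-time
trends from individual-level childhood cancer case records (diagnosis date,
age group `<1`/`1-4`/`5-9`/`10-14`, ICCC diagnostic code, behaviour,
follow-up outcome). It implements the full reporting stack used by national
paediatric registries:

* **Registry core** — delimited-text reader/writer with a column-mapping
  dialect and per-row validation, cohort filters (excluded ICCC codes
  `Id`/`IId`, registration window), IARC quality indicators (MV%, DCO%,
  NOS%, infant %, non-malignant CNS %), and an OLS trend test on the annual
  non-malignant CNS proportion.
* **Survival estimation** — cohort Kaplan–Meier with Greenwood variance and
  log(−log) 95% CIs, truncated at a horizon; the **period approach** for
  recent calendar windows (delayed entry at the window start, censoring at
  the window end), reducing exactly to Kaplan–Meier when the window covers
  all follow-up; k-group log-rank tests; risk-of-death-reduction
  arithmetic.
* **Age standardisation** — case-pool weights (each age group's share of
  the full 1999–2021 pool), adjacent-group pooling when any cohort cell
  holds fewer than 15 cases, strict small-cell suppression (< 15 cases →
  `-`), and the weighted combination Σ wₐSₐ with SE √(Σ wₐ²seₐ²).
* **Cox–joinpoint trends** — age-stratified Cox model whose log hazard is
  continuous piecewise-linear in diagnosis year,

  h_a(t|y) = h₀ₐ(t) · exp(β₀(y−y₀) + Σₖ βₖ(y−τₖ)₊),

  follow-up right-truncated at 5 years, Efron ties, Breslow baselines;
  joinpoints (0–2, each segment ≥ 3 years) selected by exhaustive grid
  search minimising BIC = −2 logPL + p·log(events); fitted
  age-standardised 5-year survival series with a delta-method 95% band,
  predicted one year past the last fitted diagnosis year; and the **AACS**
  (average absolute change in survival, percentage points/year) with a
  500-replicate case-resampling bootstrap CI (median, 2.5th/97.5th
  percentiles; joinpoint locations held fixed).
* **Synthetic registry** — a generator with piecewise-exponential ground
  truth (`trend_scenario()`, `generate_registry()`, `true_s5()`,
  `true_aacs()`) emulating a ~20,500-case national series (1999–2021,
  closure 31 Dec 2022, ~3% loss to follow-up), so the whole pipeline is
  testable without confidential data.
* **Reporting** — `run_cohort_tables()`, `run_age_sex_tables()`,
  `run_trends()` and `run_report()` orchestrate end-to-end runs (four 5-year
  cohorts 1999–2018 plus a 2019–2022 period window by default) and write
  CSV/JSON outputs with a provenance manifest.

## Worked example

```r
library(registrend)

sc <- trend_scenario(seed = 2026)            # defaults: ~890 cases/yr, 1999-2021
cases <- apply_cohort_filters(generate_registry(sc))

quality_indicators(cases)
#> IARC quality indicators (20349 cases)
#>   Microscopically verified cases (MV%)       89.6
#>   Death-certificate-only cases (DCO%)        - (not a registration source)
#>   Unspecified cases (NOS%)                   1.5
#>   Cases aged <1 year (%)                     10.7
#>   Non-malignant CNS cases (%)                31.3

# cohort estimate for the first 5-year cohort
kaplan_meier(followup_observations(cases[cases$diagnosis_year <= 2003, ]))
#> Survival curve: 4437 cases, horizon 5 years
#>   OS(1 y) = 87.3% [86.3, 88.3]
#>   OS(3 y) = 78.7% [77.5, 79.9]
#>   OS(5 y) = 76.1% [74.8, 77.3]

# up-to-date estimate for 2019-2022 via the period approach
period_survival(cases, period_window(2019, 2022))
#> Survival curve: 5866 cases, horizon 5 years
#>   OS(5 y) = 83.8% [82.5, 85.0]

# BIC-selected Cox-joinpoint trend model, stratified by age
obs <- cox_observations(cases)
m <- select_joinpoints(obs)
m
#> Cox-joinpoint model (reference year 1999)
#>   joinpoints: none
#>   segment 1 (from 1999): slope -0.0238 log-hazard/yr
#>   strata: 0-4, 10-14, 5-9; events 3877/20349; logPL -33685.950; BIC 67380.163

# age-standardised fitted 5-year survival series with AACS bootstrap CI
w <- derive_weights(cases)
ser <- adjusted_s5_series(m, w)
ser$aacs_ci <- bootstrap_aacs(obs, m$basis, w, B = 500, seed = 2026)$ci
ser
#> Age-standardised 5-year survival series, 1999-2022
#>   start 75.4%, end 84.9% (1 extrapolated year)
#>   AACS 0.41 pp/yr [0.33, 0.49]
```

Reading the output: the generator's truth has all-ages 5-year survival
rising from ~75% (1999) to ~85% (2022) with no trend break and a log-hazard
slope of −0.023/year. The pipeline recovers the flat joinpoint structure
(none selected), the slope (−0.0238), the endpoints (75.4% → 84.9%), and an
AACS of 0.41 points/year whose bootstrap interval excludes 0 — a
statistically significant improvement. The true AACS under this scenario is
`true_aacs(sc, w)` ≈ 0.40.

See the vignette (`vignettes/survival-trends.Rmd`) for the model, its
assumptions, the pooling/suppression rules, and the design decisions.

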