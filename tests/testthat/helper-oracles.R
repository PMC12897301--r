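# Independent brute-force oracles, written against the definitions rather
# than against any package code path.

# Product-limit estimator with optional delayed entry, by direct risk-set
# counting: at each distinct death time t, n(t) = #{entry < t <= time},
# d(t) = #{time == t, death}, S *= (1 - d/n). Greenwood variance
# var(S) = S^2 * sum(d / (n (n - d))). Deaths precede censorings at tied
# times by construction of the risk set (censored-at-t subjects count).
pl_oracle <- function(time, event, entry = rep(0, length(time))) {
  dt <- sort(unique(time[event == 1]))
  S <- 1
  gw <- 0
  out <- data.frame(time = dt, n_risk = NA_real_, n_event = NA_real_,
                    surv = NA_real_, var = NA_real_)
  for (i in seq_along(dt)) {
    t <- dt[i]
    n <- sum(entry < t & time >= t)
    d <- sum(time == t & event == 1)
    S <- S * (1 - d / n)
    if (n > d) gw <- gw + d / (n * (n - d))
    out$n_risk[i] <- n
    out$n_event[i] <- d
    out$surv[i] <- S
    out$var[i] <- if (S == 0) 0 else S^2 * gw  # variance degenerate at S = 0
  }
  out
}

# Step-function read-off of the oracle estimate at time t.
pl_oracle_at <- function(time, event, t, entry = rep(0, length(time))) {
  o <- pl_oracle(time, event, entry)
  rows <- o$surv[o$time <= t]
  if (length(rows) == 0) 1 else rows[length(rows)]
}

# Two-group log-rank by hypergeometric accumulation over the pooled death
# times: U = sum(d1 - n1 * d / n), V = sum(d * (n1/n) * (1 - n1/n) *
# (n - d)/(n - 1)); chi-square = U^2 / V.
logrank_oracle <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  g1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  U <- 0
  V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    U <- U + d1 - n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Cox log partial likelihood with Efron ties by direct enumeration over
# event times (no strata or one stratum at a time).
cox_pl_oracle <- function(time, event, x, beta) {
  eta <- drop(as.matrix(x) %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(w[risk]) - (l / d) * sum(w[dead]))
    }
  }
  ll
}

# 5-year cumulative hazard by numerical quadrature of a piecewise-constant
# hazard times a multiplier (checks the closed form used by the generator).
cumhaz_quadrature <- function(breaks, rates, mult, t = 5) {
  f <- function(u) {
    idx <- findInterval(u, breaks)
    rates[idx] * mult
  }
  integrate(f, 0, t, subdivisions = 2000L, rel.tol = 1e-10)$value
}

# A small registry-like data.frame built directly (bypassing the generator)
# with explicit fields; defaults give valid malignant first-primary records.
make_cases <- function(n = 10, diagnosis_year = 2005, iccc_code = "Ia",
                       age_group = "1-4", behaviour = "malignant",
                       morphology = 9835, sex = "male",
                       mv = TRUE, seq_no = 1,
                       followup_years = 5, vital_status = "alive") {
  dd <- as.Date(sprintf("%d-07-01", diagnosis_year))
  data.frame(
    case_id = sprintf("T%04d", seq_len(n)),
    diagnosis_date = rep(dd, n),
    diagnosis_year = diagnosis_year,
    age_group = age_group,
    sex = sex,
    iccc_code = iccc_code,
    behaviour = behaviour,
    morphology = morphology,
    microscopically_verified = mv,
    sequence_number = seq_no,
    vital_status = vital_status,
    followup_end_date = dd + round(followup_years * 365.25),
    stringsAsFactors = FALSE
  )
}

# Random small survival datasets with ties (one-decimal times) for
# cross-implementation checks.
random_surv_data <- function(n) {
  data.frame(time = round(rexp(n, 0.3) + 0.1, 1),
             event = rbinom(n, 1, 0.6),
             entry_time = 0)
}
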