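test_that("the year basis is a continuous hinge representation", {
  b0 <- year_basis(1999)
  expect_equal(drop(year_basis_eval(b0, 2004)), c(f0 = 5))
  b1 <- year_basis(1999, 2007)
  expect_equal(unname(year_basis_eval(b1, 2010)[1, ]), c(11, 3))
  expect_equal(unname(year_basis_eval(b1, 2007)[1, ]), c(8, 0))
  # continuity at the joinpoint: value equals both one-sided limits
  beta <- c(-0.02, -0.03)
  f <- function(y) drop(year_basis_eval(b1, y) %*% beta)
  eps <- 1e-9
  expect_equal(f(2007), f(2007 - eps), tolerance = 1e-6)
  expect_equal(f(2007), f(2007 + eps), tolerance = 1e-6)
  # segment-slope conversion round-trips
  expect_equal(coef_to_slopes(slopes_to_coef(c(-0.01, 0.04, 0))),
               c(-0.01, 0.04, 0))
  expect_error(year_basis(1999, 2001), "fewer than 3")
  expect_error(year_basis(1999, c(2005, 2006)), "closer than")
  expect_error(year_basis(1999, 2019, y_end = 2021), "after it")
})

test_that("the partial likelihood matches exhaustive enumeration on tiny fixtures", {
  # 5 subjects, one stratum, with a tie among deaths (exercises Efron)
  d <- data.frame(time = c(1, 2, 2, 3, 4), event = c(1, 1, 1, 0, 1),
                  year = c(2000, 2003, 2005, 2001, 2008),
                  stratum = "all")
  basis <- year_basis(1999)
  for (beta in c(-0.1, 0, 0.07)) {
    x <- d$year - 1999
    ours <- registrend:::cox_ll(
      d$time, d$event, cbind(x - mean(x)),
      0L, nrow(d) - 1L, beta, FALSE)$loglik
    expect_equal(ours, cox_pl_oracle(d$time, d$event, x - mean(x), beta),
                 tolerance = 1e-10)
  }
  # two strata: log partial likelihood adds over strata
  d2 <- rbind(d, transform(d, stratum = "b", time = time + 0.5))
  fit <- fit_cox(d2, basis)
  o <- cox_pl_oracle(d$time, d$event, d$year - 1999, unname(fit$beta)) +
    cox_pl_oracle(d$time + 0.5, d$event, d$year - 1999, unname(fit$beta))
  expect_equal(fit$loglik, o, tolerance = 1e-8)
})

test_that("the fit agrees with an independent reference implementation", {
  set.seed(9)
  for (r in 1:20) {
    n <- 300
    d <- data.frame(time = round(rexp(n) + 0.01, 2),
                    event = rbinom(n, 1, 0.5),
                    year = sample(1999:2021, n, TRUE),
                    stratum = sample(c("0-4", "5-9", "10-14"), n, TRUE))
    basis <- year_basis(1999)
    m <- fit_cox(d, basis)
    cf <- survival::coxph(
      survival::Surv(time, event) ~ I(year - 1999) + survival::strata(stratum),
      data = d, ties = "efron")
    expect_equal(unname(m$beta), unname(coef(cf)), tolerance = 1e-6)
    expect_equal(m$cov[1, 1], vcov(cf)[1, 1], tolerance = 1e-6)
    expect_equal(m$loglik, cf$loglik[2], tolerance = 1e-6)
    # Breslow-type baseline at the reference year (covariate 0) matches the
    # reference implementation with the Breslow cumulative-hazard estimator
    sf <- survival::survfit(cf, newdata = data.frame(year = 1999), ctype = 1)
    for (si in seq_along(m$strata)) {
      s <- names(sf$strata)[si]
      idx <- (cumsum(c(0, sf$strata))[si] + 1):cumsum(sf$strata)[si]
      ref <- max(sf$cumhaz[idx][sf$time[idx] <= 5])
      expect_equal(baseline_cumhaz(m, sub(".*=", "", s), 5), ref,
                   tolerance = 1e-6)
    }
  }
})

test_that("a true hazard ratio is recovered consistently (two-group toy)", {
  # two 'years' acting as groups with hazard ratio 2: beta-hat -> ln 2
  set.seed(12)
  est <- function(n) {
    t1 <- rexp(n, 1)
    t2 <- rexp(n, 2)
    d <- data.frame(time = c(t1, t2), event = 1,
                    year = rep(c(2000, 2001), each = n), stratum = "all")
    unname(fit_cox(d, year_basis(2000))$beta)
  }
  e_small <- abs(est(150) - log(2))
  e_large <- abs(est(6000) - log(2))
  expect_lt(e_large, 0.06)
  expect_lt(e_large, e_small)
})

test_that("null-trend estimates are unbiased with near-nominal CI coverage", {
  set.seed(19)
  reps <- 500
  cover <- 0
  z <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 400
    d <- data.frame(time = pmin(rexp(n, 0.2), 5),
                    year = sample(1999:2021, n, TRUE),
                    stratum = "all")
    d$event <- as.integer(d$time < 5)
    m <- fit_cox(d, year_basis(1999))
    se <- sqrt(m$cov[1, 1])
    z[r] <- m$beta / se
    if (abs(m$beta) <= qnorm(0.975) * se) cover <- cover + 1
  }
  # Wald intervals are mildly anticonservative at this n; near-nominal means
  # a couple of points below 95% at most
  expect_gt(cover / reps, 0.91)
  expect_lte(cover / reps, 0.98)
  expect_lt(abs(mean(z)), 3 / sqrt(reps))  # unbiased: mean z near 0
})

test_that("partial likelihood is invariant to re-centring the year covariate", {
  set.seed(23)
  n <- 500
  d <- data.frame(time = round(rexp(n) + 0.01, 2), event = rbinom(n, 1, 0.6),
                  year = sample(1999:2021, n, TRUE), stratum = "all")
  m1 <- fit_cox(d, year_basis(1999))
  d2 <- transform(d, year = year - 10)
  m2 <- fit_cox(d2, year_basis(1989))
  expect_equal(unname(m1$beta), unname(m2$beta), tolerance = 1e-8)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-8)
  expect_equal(m1$cov, m2$cov, tolerance = 1e-8)
})

test_that("BIC components follow the events-based penalty", {
  set.seed(3)
  n <- 200
  d <- data.frame(time = round(rexp(n) + 0.01, 2), event = rbinom(n, 1, 0.5),
                  year = sample(1999:2021, n, TRUE), stratum = "all")
  m <- fit_cox(d, year_basis(1999))
  expect_equal(m$bic, -2 * m$loglik + 1 * log(m$n_events), tolerance = 1e-12)
  # hand arithmetic check of the formula on stated components
  fake <- structure(list(loglik = -10, n_events = 20, beta = 0.1,
                         basis = year_basis(1999)), class = "coxjp")
  expect_equal(bic(fake), 20 + log(20), tolerance = 1e-12)
  fake2 <- structure(list(loglik = -10, n_events = 20, beta = c(0.1, 0),
                          basis = year_basis(1999, 2008)), class = "coxjp")
  expect_gt(bic(fake2), bic(fake))  # equal fit, more parameters
  expect_equal(bic(fake2, count_joinpoints = TRUE), 20 + 3 * log(20),
               tolerance = 1e-12)
  # nesting: adding a joinpoint never lowers the maximised log likelihood
  m1 <- fit_cox(d, year_basis(1999, 2010))
  expect_gte(m1$loglik, m$loglik - 1e-8)
})

test_that("the joinpoint grid search is exhaustive with deterministic tie-breaks", {
  set.seed(44)
  n <- 800
  d <- data.frame(time = round(rexp(n, 0.3) + 0.01, 2),
                  event = rbinom(n, 1, 0.5),
                  year = sample(1999:2012, n, TRUE), stratum = "all")
  sel <- select_joinpoints(d, max_joinpoints = 1, min_segment = 3)
  # direct scan over the admissible grid
  best_bic <- fit_cox(d, year_basis(1999))$bic
  for (tau in 2002:2009) {
    best_bic <- min(best_bic, fit_cox(d, year_basis(1999, tau))$bic)
  }
  expect_equal(sel$bic, best_bic, tolerance = 1e-9)
  # earliest admissible joinpoint leaves min_segment years before it
  taus <- sel$grid$joinpoints[sel$grid$n_joinpoints == 1]
  expect_equal(min(as.integer(taus)), 2002)
  expect_equal(max(as.integer(taus)), 2009)
})

test_that("fit preconditions are enforced", {
  d <- data.frame(time = c(1, 2), event = c(0, 0), year = c(2000, 2001),
                  stratum = "all")
  expect_error(fit_cox(d, year_basis(1999)), "no events")
  d2 <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                   year = c(2000, 2001, 2002),
                   stratum = c("0-4", "0-4", "5-9"))
  expect_error(fit_cox(d2, year_basis(1999)), "stratum without events")
})

test_that("the adjusted series is flat without a trend and matches its formula", {
  set.seed(55)
  n <- 2500
  d <- data.frame(time = pmin(rexp(n, 0.15), 5),
                  year = sample(1999:2021, n, TRUE),
                  stratum = sample(c("0-4", "5-9"), n, TRUE))
  d$event <- as.integer(d$time < 5)
  m <- fit_cox(d, year_basis(1999))
  w <- age_weights(c("0-4", "5-9"), c(0.6, 0.4))
  ser <- adjusted_s5_series(m, w, years = 1999:2022)
  # direct formula: S = sum w_a exp(-Lambda_a(5) exp(beta (y - 1999)))
  for (i in c(1, 12, 24)) {
    y <- ser$years[i]
    expected <- sum(w$weights * sapply(c("0-4", "5-9"), function(g)
      exp(-baseline_cumhaz(m, g, 5) * exp(unname(m$beta) * (y - 1999)))))
    expect_equal(ser$s5[i], expected, tolerance = 1e-12)
  }
  expect_true(all(ser$s5 >= 0 & ser$s5 <= 1))
  expect_true(all(ser$band_low <= ser$s5 + 1e-12))
  expect_true(all(ser$band_high >= ser$s5 - 1e-12))
  expect_equal(ser$extrapolated, ser$years > 2021)
  expect_error(adjusted_s5_series(m, age_weights("0-14", 1)),
               "does not match")
})

test_that("AACS arithmetic matches its definition, full-series and per-segment", {
  flat <- list(years = 1999:2022, s5 = rep(0.8, 24))
  expect_equal(aacs(flat), 0)
  rising <- list(years = 1999:2022, s5 = seq(0.80, 0.915, length.out = 24))
  expect_equal(aacs(rising), 0.5, tolerance = 1e-12)
  # endpoints like a Burkitt-lymphoma series: 84.05% -> 99.0% over 24 years
  bl <- list(years = 1999:2022, s5 = seq(0.8405, 0.99, length.out = 24))
  expect_equal(aacs(bl), 0.65, tolerance = 1e-10)
  # per-segment read-off
  piece <- list(years = 1999:2009,
                s5 = c(rep(0.7, 4), seq(0.7, 0.82, by = 0.02)))
  expect_equal(aacs(piece, from = 2003, to = 2009), 2, tolerance = 1e-10)
  expect_error(aacs(list(years = 2000, s5 = 0.5)), "two years")
})

test_that("well-specified fits recover the standardised truth within the band", {
  set.seed(66)
  hits <- 0
  total <- 0
  for (r in 1:8) {
    sc <- trend_scenario(annual_cases = c("<1" = 30, "1-4" = 90, "5-9" = 75,
                                          "10-14" = 70),
                         segment_slopes = -0.025, seed = 900 + r)
    cases <- apply_cohort_filters(generate_registry(sc))
    obs <- cox_observations(cases)
    m <- fit_cox(obs, year_basis(1999))
    w <- derive_weights(cases)
    ser <- adjusted_s5_series(m, w, years = 1999:2022)
    truth <- sapply(ser$years, function(y) {
      sum(sapply(seq_along(w$grouping), function(i) {
        g <- w$grouping[i]
        members <- if (g == "0-4") c("<1", "1-4") else g
        wm <- sc$annual_cases[members]
        w$weights[i] * sum(wm * sapply(members, function(a)
          true_s5(sc, y, a))) / sum(wm)
      }))
    })
    hits <- hits + sum(truth >= ser$band_low & truth <= ser$band_high)
    total <- total + length(truth)
  }
  expect_gt(hits / total, 0.80)  # joint-band hit rate; pointwise nominal 95%
})

test_that("the AACS bootstrap is reproducible and internally ordered", {
  sc <- trend_scenario(annual_cases = c("<1" = 25, "1-4" = 70, "5-9" = 60,
                                        "10-14" = 55), seed = 31)
  cases <- apply_cohort_filters(generate_registry(sc))
  obs <- cox_observations(cases)
  w <- derive_weights(cases)
  b1 <- bootstrap_aacs(obs, year_basis(1999), w, B = 40, seed = 123)
  b2 <- bootstrap_aacs(obs, year_basis(1999), w, B = 40, seed = 123)
  expect_identical(b1, b2)
  expect_gte(b1$median, b1$ci[1])
  expect_lte(b1$median, b1$ci[2])
  b3 <- bootstrap_aacs(obs, year_basis(1999), w, B = 40, seed = 124)
  expect_false(identical(b1$draws, b3$draws))
})
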