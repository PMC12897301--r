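# Synthetic registry generator: piecewise-exponential survival with a
# continuous piecewise-linear calendar-year effect on the log hazard, plus
# independent exponential loss to follow-up and administrative censoring.

#' Define a synthetic registry scenario
#'
#' The scenario fixes the data-generating truth for a registry-like case
#' series: annual expected case counts per age group, per-age-group
#' piecewise-constant baseline hazards over follow-up time, a piecewise-linear
#' log-hazard trend in diagnosis year (0-2 joinpoints), an independent
#' exponential loss-to-follow-up process, and administrative closure.
#' Defaults emulate a national childhood-cancer series: 23 incidence years
#' (1999-2021), roughly 890 cases per year (about 20,500 in total), baseline
#' 5-year survival near 75\% in 1999 rising to about 85\% by the series end,
#' and ~3\% of cases lost to follow-up within 5 years.
#'
#' @param years inclusive diagnosis-year range.
#' @param annual_cases named numeric vector of expected cases per year for
#'   each age group `<1`, `1-4`, `5-9`, `10-14`.
#' @param hazard_breaks left endpoints of the follow-up intervals (years
#'   since diagnosis) on which the baseline hazard is constant; the last
#'   interval extends to infinity.
#' @param baseline_hazards named list, one numeric vector of hazards
#'   (events/person-year, one per interval) per age group.
#' @param joinpoints 0-2 integer calendar years, interior to `years`.
#' @param segment_slopes per-segment slope of the log hazard per calendar
#'   year (length `length(joinpoints) + 1`); negative values mean improving
#'   survival.
#' @param ltfu_rate annual loss-to-follow-up hazard.
#' @param admin_close administrative closure date.
#' @param male_share probability a case is male.
#' @param second_tumour_rate probability a case is a second (or later)
#'   primary.
#' @param mv_prob probability a case is microscopically verified.
#' @param tumour_mix data.frame with columns `iccc_code`, `share` (relative
#'   frequency, normalised internally), `p_nonmalignant`, and `morphology`
#'   (representative histology code).
#' @param seed integer seed making generation reproducible.
#' @return a validated `trend_scenario` object.
#' @export
trend_scenario <- function(years = 1999:2021,
                           annual_cases = c("<1" = 97, "1-4" = 312,
                                            "5-9" = 250, "10-14" = 234),
                           hazard_breaks = c(0, 1, 3, 5),
                           baseline_hazards = list(
                             "<1"    = c(0.20, 0.060, 0.020, 0.010),
                             "1-4"   = c(0.12, 0.050, 0.015, 0.008),
                             "5-9"   = c(0.13, 0.055, 0.018, 0.008),
                             "10-14" = c(0.15, 0.060, 0.020, 0.010)),
                           joinpoints = integer(0),
                           segment_slopes = -0.023,
                           ltfu_rate = 0.006,
                           admin_close = as.Date("2022-12-31"),
                           male_share = 0.55,
                           second_tumour_rate = 0.006,
                           mv_prob = 0.895,
                           tumour_mix = default_tumour_mix(),
                           seed = 1L) {
  years <- as.integer(years)
  stopifnot(length(years) >= 2, !is.unsorted(years, strictly = TRUE))
  if (!setequal(names(annual_cases), AGE_GROUPS) ||
      !setequal(names(baseline_hazards), AGE_GROUPS)) {
    stop("annual_cases and baseline_hazards must be named by the four age groups")
  }
  if (any(annual_cases <= 0)) stop("expected annual case counts must be > 0")
  nb <- length(hazard_breaks)
  if (hazard_breaks[1] != 0 || is.unsorted(hazard_breaks, strictly = TRUE)) {
    stop("hazard_breaks must start at 0 and increase strictly")
  }
  for (a in AGE_GROUPS) {
    h <- baseline_hazards[[a]]
    if (length(h) != nb || any(h < 0)) {
      stop("baseline hazards for ", a, " must be ", nb, " non-negative rates")
    }
  }
  joinpoints <- as.integer(joinpoints)
  if (length(joinpoints) > 2) stop("at most 2 joinpoints supported")
  if (length(joinpoints) > 0 &&
      (is.unsorted(joinpoints, strictly = TRUE) ||
       any(joinpoints <= min(years)) || any(joinpoints >= max(years)))) {
    stop("joinpoints must be strictly increasing and interior to the year range")
  }
  if (length(segment_slopes) != length(joinpoints) + 1) {
    stop("need one segment slope per segment (joinpoints + 1)")
  }
  if (ltfu_rate < 0) stop("ltfu_rate must be >= 0")
  admin_close <- as.Date(admin_close)
  if (as.integer(format(admin_close, "%Y")) < max(years)) {
    stop("admin_close precedes the last diagnosis year")
  }
  req <- c("iccc_code", "share", "p_nonmalignant", "morphology")
  if (!all(req %in% names(tumour_mix))) {
    stop("tumour_mix must have columns ", paste(req, collapse = ", "))
  }
  tumour_mix$share <- tumour_mix$share / sum(tumour_mix$share)
  structure(list(
    years = years, annual_cases = annual_cases,
    hazard_breaks = hazard_breaks, baseline_hazards = baseline_hazards,
    joinpoints = joinpoints, segment_slopes = as.numeric(segment_slopes),
    ltfu_rate = ltfu_rate, admin_close = admin_close,
    male_share = male_share, second_tumour_rate = second_tumour_rate,
    mv_prob = mv_prob, tumour_mix = tumour_mix, seed = as.integer(seed)
  ), class = "trend_scenario")
}

#' Default synthetic tumour mix
#'
#' Relative ICCC-code frequencies loosely shaped like a paediatric registry:
#' leukaemias and CNS tumours dominate, about a third of CNS tumours are
#' non-malignant, and small shares of the excluded codes `Id`/`IId` are
#' included so that cohort filtering is exercised.
#'
#' @return data.frame with `iccc_code`, `share`, `p_nonmalignant`,
#'   `morphology`.
#' @export
default_tumour_mix <- function() {
  data.frame(
    iccc_code = c("Ia", "Ia", "Ib", "Id", "IIa", "IIb", "IIc", "IId",
                  "IIIa", "IIIb", "IIIc", "IIId", "IIIf",
                  "IVa", "V", "VIa", "VIc", "VIIa", "VIIIa", "VIIIc",
                  "IXa", "IXb", "Xa", "Xb", "Xc", "XIa", "XIb"),
    share = c(0.238, 0.005, 0.045, 0.010, 0.050, 0.030, 0.025, 0.005,
              0.040, 0.115, 0.050, 0.020, 0.006,
              0.080, 0.030, 0.050, 0.004, 0.020, 0.030, 0.030,
              0.040, 0.020, 0.015, 0.010, 0.015, 0.010, 0.007),
    p_nonmalignant = c(0, 0, 0, 0, 0, 0, 0, 0,
                       0.07, 0.57, 0, 0.20, 0.20,
                       0, 0, 0, 0, 0, 0, 0,
                       0, 0, 0.35, 0, 0, 0, 0),
    morphology = c(9835L, 9800L, 9861L, 9950L, 9650L, 9591L, 9687L, 9750L,
                   9391L, 9400L, 9470L, 9380L, 8000L,
                   9500L, 9510L, 8960L, 8000L, 8970L, 9180L, 9260L,
                   8900L, 9040L, 9064L, 9080L, 9085L, 8010L, 8330L),
    stringsAsFactors = FALSE
  )
}

# log hazard-ratio multiplier eta(year) implied by the scenario's
# piecewise-linear trend, relative to the first diagnosis year.
scenario_eta <- function(scenario, year) {
  basis <- year_basis(min(scenario$years), scenario$joinpoints)
  X <- year_basis_eval(basis, year)
  drop(X %*% slopes_to_coef(scenario$segment_slopes))
}

# Baseline cumulative hazard at time t (years since diagnosis) for one age
# group, from the piecewise-constant rates.
scenario_cumhaz <- function(scenario, age_group, t) {
  breaks <- scenario$hazard_breaks
  rates <- scenario$baseline_hazards[[age_group]]
  upper <- c(breaks[-1], Inf)
  vapply(t, function(ti) {
    width <- pmax(0, pmin(ti, upper) - breaks)
    sum(rates * width)
  }, numeric(1))
}

# Vectorised sampler from a piecewise-exponential distribution: baseline
# rates per interval scaled by a per-subject multiplier. Returns Inf when
# the total hazard is exhausted (e.g. all rates zero).
sample_piecewise_exp <- function(target, breaks, rates, mult) {
  n <- length(target)
  upper <- c(breaks[-1], Inf)
  t <- rep(Inf, n)
  remaining <- target
  done <- rep(FALSE, n)
  for (i in seq_along(breaks)) {
    r <- rates[i] * mult
    width <- upper[i] - breaks[i]
    hz <- ifelse(r > 0, r * width, 0)
    cross <- !done & remaining <= hz & r > 0
    t[cross] <- breaks[i] + remaining[cross] / r[cross]
    remaining[!cross & !done] <- remaining[!cross & !done] - hz[!cross & !done]
    done <- done | cross
  }
  t
}

#' Generate a synthetic registry case table
#'
#' Draws annual case counts from Poisson distributions around the scenario's
#' expected counts, diagnosis dates uniformly within each year, death times
#' from the piecewise-exponential model with hazard
#' `h_a(t) * exp(eta(year))`, and independent exponential loss to follow-up.
#' Follow-up ends at the earliest of death, loss and administrative closure;
#' the 5-year right-truncation used by the trend models is an analysis step
#' and is deliberately not applied here.
#'
#' @param scenario a [trend_scenario()].
#' @return a `registry_cases` table; generation is reproducible under the
#'   scenario's seed.
#' @export
generate_registry <- function(scenario) {
  stopifnot(inherits(scenario, "trend_scenario"))
  set.seed(scenario$seed)
  years <- scenario$years
  mix <- scenario$tumour_mix
  rows <- vector("list", length(years) * length(AGE_GROUPS))
  k <- 0
  for (y in years) {
    year_start <- as.Date(sprintf("%d-01-01", y))
    days_in_year <- as.integer(as.Date(sprintf("%d-01-01", y + 1)) - year_start)
    eta <- scenario_eta(scenario, y)
    for (a in AGE_GROUPS) {
      n <- rpois(1, scenario$annual_cases[[a]])
      if (n == 0) next
      diagnosis_date <- year_start + sample.int(days_in_year, n, replace = TRUE) - 1L
      death <- sample_piecewise_exp(rexp(n), scenario$hazard_breaks,
                                    scenario$baseline_hazards[[a]],
                                    rep(exp(eta), n))
      loss <- if (scenario$ltfu_rate > 0) rexp(n, scenario$ltfu_rate) else rep(Inf, n)
      admin <- as.numeric(scenario$admin_close - diagnosis_date) / DAYS_PER_YEAR
      t <- pmin(death, loss, admin)
      status <- ifelse(death <= pmin(loss, admin), "dead",
                       ifelse(loss < admin, "lost", "alive"))
      mix_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$share)
      behaviour <- ifelse(runif(n) < mix$p_nonmalignant[mix_idx],
                          "non_malignant", "malignant")
      followup_days <- pmax(1, round(t * DAYS_PER_YEAR))
      followup_end <- pmin(diagnosis_date + followup_days, scenario$admin_close)
      k <- k + 1
      rows[[k]] <- data.frame(
        diagnosis_date = diagnosis_date,
        diagnosis_year = y,
        age_group = a,
        sex = ifelse(runif(n) < scenario$male_share, "male", "female"),
        iccc_code = mix$iccc_code[mix_idx],
        behaviour = behaviour,
        morphology = mix$morphology[mix_idx],
        microscopically_verified = runif(n) < scenario$mv_prob,
        sequence_number = ifelse(runif(n) < scenario$second_tumour_rate, 2L, 1L),
        vital_status = status,
        followup_end_date = followup_end,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows[seq_len(k)])
  df$case_id <- sprintf("S%06d", seq_len(nrow(df)))
  registry_cases(df)
}

#' True 5-year survival under a scenario
#'
#' Closed-form ground truth from the piecewise-exponential generative model:
#' `S_a(5 | y) = exp(-Lambda_a(5) * exp(eta(y)))`, where `Lambda_a(5)` is the
#' baseline cumulative hazard of age group `a` at 5 years and `eta` the
#' piecewise-linear year effect.
#'
#' @param scenario a [trend_scenario()].
#' @param year diagnosis year(s); must lie between the first scenario year
#'   and the administrative-closure year (predictions beyond the last
#'   diagnosis year continue the last segment).
#' @param age_group one of the four age groups.
#' @return numeric vector of survival probabilities.
#' @export
true_s5 <- function(scenario, year, age_group) {
  stopifnot(inherits(scenario, "trend_scenario"))
  admin_year <- as.integer(format(scenario$admin_close, "%Y"))
  if (any(year < min(scenario$years)) || any(year > admin_year)) {
    stop("year outside the scenario range [", min(scenario$years), ", ",
         admin_year, "]")
  }
  if (!age_group %in% AGE_GROUPS) stop("unknown age group: ", age_group)
  lam5 <- scenario_cumhaz(scenario, age_group, 5)
  exp(-lam5 * exp(scenario_eta(scenario, year)))
}

#' True average absolute change in survival (AACS) under a scenario
#'
#' Standardised true 5-year survival at the final series year (the
#' administrative-closure year) minus at the first year, times 100, divided
#' by the number of year-to-year intervals.
#'
#' @param scenario a [trend_scenario()].
#' @param weights an [age_weights()] object over (possibly pooled) age
#'   groups.
#' @return AACS in percentage points per year.
#' @export
true_aacs <- function(scenario, weights) {
  admin_year <- as.integer(format(scenario$admin_close, "%Y"))
  y_first <- min(scenario$years)
  std_s5 <- function(y) {
    # pooled groups average their member groups' truth weighted by expected
    # case counts, matching how a pooled stratum would be populated
    contains <- list(
      "<1" = "<1", "1-4" = "1-4", "5-9" = "5-9", "10-14" = "10-14",
      "0-4" = c("<1", "1-4"), "0-9" = c("<1", "1-4", "5-9"),
      "5-14" = c("5-9", "10-14"), "0-14" = AGE_GROUPS
    )
    s <- vapply(weights$grouping, function(g) {
      members <- contains[[g]]
      w <- scenario$annual_cases[members]
      sum(w * vapply(members, function(a) true_s5(scenario, y, a), numeric(1))) / sum(w)
    }, numeric(1))
    sum(weights$weights * s)
  }
  (std_s5(admin_year) - std_s5(y_first)) * 100 / (admin_year - y_first)
}
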