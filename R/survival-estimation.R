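# Cohort Kaplan-Meier, log-rank comparisons, and the period approach for
# incomplete recent cohorts. Product-limit computation is delegated to
# survival::survfit (Greenwood variance, log(-log) confidence intervals,
# delayed entry via counting-process input); this file owns the registry
# semantics: time conversion, horizon truncation, and calendar-window
# clipping at day resolution.

#' Follow-up observations from case records
#'
#' Converts case records to analysis observations: `time` in years since
#' diagnosis (`days / 365.25`, with same-day outcomes set to half a day so
#' that no zero-length interval enters the risk sets), `event` (1 = death,
#' 0 = censored; loss to follow-up censors), and `entry_time = 0` (cohort
#' analyses; the period approach sets its own delayed entry).
#'
#' @param cases a `registry_cases` table.
#' @return data.frame with columns `entry_time`, `time`, `event`,
#'   `diagnosis_year`, `age_group`, `sex`.
#' @export
followup_observations <- function(cases) {
  days <- as.numeric(cases$followup_end_date - cases$diagnosis_date)
  data.frame(
    entry_time = numeric(length(days)),
    time = pmax(days, 0.5) / DAYS_PER_YEAR,
    event = as.integer(cases$vital_status == "dead"),
    diagnosis_year = cases$diagnosis_year,
    age_group = as.character(cases$age_group),
    sex = as.character(cases$sex),
    stringsAsFactors = FALSE
  )
}

# Wrap a survfit object (single stratum) into the package's curve container.
as_survival_curve <- function(fit, n_total, horizon) {
  s <- summary(fit, censored = TRUE)
  keep <- s$time <= horizon + 1e-12
  curve <- data.frame(
    time = s$time[keep],
    n_risk = s$n.risk[keep],
    n_event = s$n.event[keep],
    surv = s$surv[keep],
    var = s$std.err[keep]^2,
    ci_low = pmin(pmax(s$lower[keep], 0), 1),
    ci_high = pmin(pmax(s$upper[keep], 0), 1)
  )
  # no events => variance exactly 0, CI degenerate at the estimate
  none <- curve$n_event == 0 & curve$surv == 1
  curve$ci_low[none] <- 1
  curve$ci_high[none] <- 1
  curve$var[is.na(curve$var)] <- 0
  structure(list(steps = curve, n_total = n_total, horizon = horizon),
            class = "survival_curve")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of overall survival, truncated at `horizon` years
#' (observations beyond the horizon are censored at the horizon), with
#' Greenwood variance and 95\% confidence intervals on the log(-log) scale
#' clipped to \[0, 1\]. Deaths precede censorings at tied times, the
#' standard product-limit convention.
#'
#' @param observations data.frame with columns `time` (> 0, years) and
#'   `event` (1 = death); `entry_time` must be 0 (use [period_survival()]
#'   for delayed entry).
#' @param horizon truncation horizon in years (default 5).
#' @return a `survival_curve` object.
#' @export
kaplan_meier <- function(observations, horizon = 5) {
  if (nrow(observations) == 0) stop("cannot estimate survival from no observations")
  if (!is.null(observations$entry_time) && any(observations$entry_time != 0)) {
    stop("kaplan_meier expects entry_time 0; use period_survival for delayed entry")
  }
  if (any(observations$time <= 0)) stop("follow-up times must be positive")
  time <- pmin(observations$time, horizon)
  event <- ifelse(observations$time > horizon, 0L, observations$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  as_survival_curve(fit, nrow(observations), horizon)
}

#' Read a survival curve at a time point
#'
#' Right-continuous step-function read-off: the estimate just after the last
#' event time at or before `t`, with its confidence interval. If `t` lies
#' beyond the last observed time while subjects were still at risk, the last
#' available estimate is returned flagged `immature`.
#'
#' @param curve a `survival_curve`.
#' @param t time in years (must not exceed the curve's horizon).
#' @return list with `surv`, `ci_low`, `ci_high`, `var`, `immature`.
#' @export
os_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (t > curve$horizon + 1e-12) stop("t exceeds the estimation horizon")
  steps <- curve$steps
  idx <- which(steps$time <= t + 1e-12)
  if (length(idx) == 0) {
    return(list(surv = 1, ci_low = 1, ci_high = 1, var = 0, immature = FALSE))
  }
  i <- max(idx)
  immature <- t > max(steps$time) + 1e-12 && steps$n_risk[i] - steps$n_event[i] > 0
  list(surv = steps$surv[i], ci_low = steps$ci_low[i],
       ci_high = steps$ci_high[i], var = steps$var[i], immature = immature)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve:", x$n_total, "cases, horizon", x$horizon, "years\n")
  for (t in c(1, 3, 5)) {
    if (t <= x$horizon) {
      e <- os_at(x, t)
      cat(sprintf("  OS(%d y) = %.1f%% [%.1f, %.1f]\n",
                  t, 100 * e$surv, 100 * e$ci_low, 100 * e$ci_high))
    }
  }
  invisible(x)
}

#' Export a survival curve as CSV or JSON
#'
#' @param curve a `survival_curve`.
#' @param path output path; format chosen by extension (`.json` or CSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  df <- curve$steps[c("time", "n_risk", "n_event", "surv", "ci_low", "ci_high")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n_total = curve$n_total, horizon = curve$horizon,
                              steps = df), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' k-group log-rank test
#'
#' Standard log-rank comparison of two or more survival distributions,
#' with `k - 1` degrees of freedom.
#'
#' @param groups list of >= 2 observation data.frames (columns `time`,
#'   `event`), one per group.
#' @param horizon optional truncation horizon in years applied to every
#'   group before testing.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(groups, horizon = NULL) {
  if (length(groups) < 2) stop("log-rank test needs at least two groups")
  if (any(vapply(groups, nrow, integer(1)) == 0)) {
    stop("log-rank test requires every group to be non-empty")
  }
  df <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(time = g$time, event = g$event, group = i)
  }))
  if (!is.null(horizon)) {
    df$event <- ifelse(df$time > horizon, 0L, df$event)
    df$time <- pmin(df$time, horizon)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(groups)
  list(chisq = unname(fit$chisq), df = k - 1L,
       p_value = pchisq(fit$chisq, k - 1L, lower.tail = FALSE))
}

#' Define a period-analysis calendar window
#'
#' A calendar window for period survival estimation. By default the
#' eligible diagnosis years run from `calendar_start - horizon + 1` (cases
#' that can still contribute follow-up inside the window) to
#' `calendar_end - 1` (the final calendar year is kept as follow-up only,
#' since cases diagnosed in it have no follow-up data yet).
#'
#' @param calendar_start,calendar_end inclusive calendar years of the
#'   window (e.g. 2019 and 2022).
#' @param horizon survival horizon in years (default 5).
#' @param diagnosis_years optional override of the eligible diagnosis years.
#' @return a `period_window` object.
#' @export
period_window <- function(calendar_start, calendar_end, horizon = 5,
                          diagnosis_years = NULL) {
  stopifnot(calendar_end >= calendar_start)
  if (is.null(diagnosis_years)) {
    diagnosis_years <- (calendar_start - horizon + 1):(calendar_end - 1)
  }
  structure(list(calendar_start = as.integer(calendar_start),
                 calendar_end = as.integer(calendar_end),
                 horizon = horizon,
                 diagnosis_years = as.integer(diagnosis_years)),
            class = "period_window")
}

# Clip each case's follow-up to the part lying inside the calendar window,
# at day resolution. Returns delayed-entry observations; cases contributing
# no positive person-time inside the window are dropped.
clip_to_window <- function(cases, window) {
  cases <- cases[cases$diagnosis_year %in% window$diagnosis_years, , drop = FALSE]
  if (nrow(cases) == 0) {
    return(data.frame(entry_time = numeric(0), time = numeric(0),
                      event = integer(0)))
  }
  win_start <- as.Date(sprintf("%d-01-01", window$calendar_start))
  win_end <- as.Date(sprintf("%d-12-31", window$calendar_end))
  entry_days <- pmax(0, as.numeric(win_start - cases$diagnosis_date))
  horizon_days <- window$horizon * DAYS_PER_YEAR
  exit_days <- pmin(as.numeric(cases$followup_end_date - cases$diagnosis_date),
                    as.numeric(win_end - cases$diagnosis_date),
                    horizon_days)
  # death counts as an event only if it happens inside the window and horizon
  death_days <- as.numeric(cases$followup_end_date - cases$diagnosis_date)
  event <- as.integer(cases$vital_status == "dead" &
                        death_days <= exit_days + 1e-9)
  keep <- exit_days > entry_days
  data.frame(entry_time = entry_days[keep] / DAYS_PER_YEAR,
             time = exit_days[keep] / DAYS_PER_YEAR,
             event = event[keep])
}

#' Period-approach survival estimation
#'
#' Estimates up-to-date survival for a recent calendar window from the
#' conditional survival experience observed inside it: each case enters the
#' risk set at `max(0, window start - diagnosis)` years since diagnosis
#' (delayed entry) and exits at the earliest of its follow-up end, the
#' window end and the horizon, with death counted as an event only when it
#' falls inside the window. The estimate is a product-limit over the clipped
#' observations with time-varying risk sets; when the window covers all
#' follow-up it reduces exactly to [kaplan_meier()].
#'
#' @param cases a `registry_cases` table.
#' @param window a [period_window()].
#' @return a `survival_curve` object; `n_total` counts cases contributing
#'   person-time inside the window.
#' @export
period_survival <- function(cases, window) {
  obs <- clip_to_window(cases, window)
  if (nrow(obs) == 0) stop("no person-time falls inside the period window")
  fit <- survival::survfit(
    survival::Surv(entry_time, time, event) ~ 1, data = obs,
    conf.type = "log-log", conf.int = 0.95
  )
  as_survival_curve(fit, nrow(obs), window$horizon)
}

#' Reduction in 5-year risk of death between two survival levels
#'
#' `100 * (1 - (100 - s_late) / (100 - s_early))`: the percentage by which
#' the risk of death within 5 years fell between an early and a late
#' estimate, both given as survival percentages.
#'
#' @param s_early,s_late survival percentages in (0, 100\]; `s_early` must
#'   be below 100 for the risk ratio to be defined.
#' @return percentage reduction in the risk of death (negative if risk
#'   increased).
#' @export
risk_reduction <- function(s_early, s_late) {
  stopifnot(s_early > 0, s_early <= 100, s_late > 0, s_late <= 100)
  if (s_early == 100) stop("risk reduction undefined: no early risk of death")
  100 * (1 - (100 - s_late) / (100 - s_early))
}
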