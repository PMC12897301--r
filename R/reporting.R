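# End-to-end orchestration: cohort/period survival tables, age- and
# sex-specific tables with log-rank tests, and fitted trend series per
# tumour group, with small-cell suppression applied at the reporting edge.

#' Define a tumour-group selection
#'
#' Selects cases by ICCC diagnostic group and/or explicit codes, optionally
#' restricted by behaviour.
#'
#' @param label display label for tables.
#' @param groups ICCC diagnostic groups (roman numerals) to include; `NULL`
#'   selects all.
#' @param codes explicit ICCC group/subgroup codes to include (overrides
#'   `groups` when given).
#' @param behaviour optional `"malignant"` or `"non_malignant"` restriction.
#' @param standardise `FALSE` for tumours exempt from age standardisation
#'   (crude estimates passed through).
#' @param direction_hint merge direction for [pool_age_groups()].
#' @return a `tumour_group` list.
#' @export
tumour_group <- function(label, groups = NULL, codes = NULL,
                         behaviour = NULL, standardise = TRUE,
                         direction_hint = "none") {
  structure(list(label = label, groups = groups, codes = codes,
                 behaviour = behaviour, standardise = standardise,
                 direction_hint = direction_hint),
            class = "tumour_group")
}

select_tumour_group <- function(cases, group) {
  keep <- rep(TRUE, nrow(cases))
  if (!is.null(group$codes)) {
    keep <- keep & cases$iccc_code %in% group$codes
  } else if (!is.null(group$groups)) {
    keep <- keep & iccc_parse(cases$iccc_code)$group %in% group$groups
  }
  if (!is.null(group$behaviour)) {
    keep <- keep & as.character(cases$behaviour) == group$behaviour
  }
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run configuration for end-to-end reporting
#'
#' @param cohorts list of inclusive diagnosis-year ranges (the 5-year
#'   cohorts); must be disjoint and ordered.
#' @param period a [period_window()] for the most recent calendar window.
#' @param groups list of [tumour_group()] selections.
#' @param age_sex_cohort diagnosis-year range for the age/sex tables.
#' @param min_cases suppression threshold.
#' @param max_joinpoints,min_segment,bootstrap_reps trend-model settings.
#' @param seed seed for the AACS bootstrap.
#' @param output_dir optional directory for CSV/JSON outputs and the run
#'   manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(cohorts = list(c(1999, 2003), c(2004, 2008),
                                      c(2009, 2013), c(2014, 2018)),
                       period = period_window(2019, 2022),
                       groups = list(tumour_group("All tumours")),
                       age_sex_cohort = c(2009, 2018),
                       min_cases = 15,
                       max_joinpoints = 2, min_segment = 3,
                       bootstrap_reps = 500, seed = 1,
                       output_dir = NULL) {
  starts <- vapply(cohorts, `[`, numeric(1), 1)
  ends <- vapply(cohorts, `[`, numeric(1), 2)
  if (any(diff(starts) <= 0) || any(ends < starts) ||
      any(head(ends, -1) >= tail(starts, -1))) {
    stop("cohorts must be ordered, disjoint year ranges")
  }
  structure(list(cohorts = cohorts, period = period, groups = groups,
                 age_sex_cohort = age_sex_cohort, min_cases = min_cases,
                 max_joinpoints = max_joinpoints, min_segment = min_segment,
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

km_row <- function(obs, min_cases) {
  n <- nrow(obs)
  if (n < min_cases) {
    return(data.frame(n = n, os1 = NA_real_, os1_low = NA_real_, os1_high = NA_real_,
                      os3 = NA_real_, os3_low = NA_real_, os3_high = NA_real_,
                      os5 = NA_real_, os5_low = NA_real_, os5_high = NA_real_,
                      suppressed = TRUE))
  }
  curve <- kaplan_meier(obs, horizon = 5)
  vals <- lapply(c(1, 3, 5), function(t) os_at(curve, t))
  data.frame(n = n,
             os1 = 100 * vals[[1]]$surv, os1_low = 100 * vals[[1]]$ci_low,
             os1_high = 100 * vals[[1]]$ci_high,
             os3 = 100 * vals[[2]]$surv, os3_low = 100 * vals[[2]]$ci_low,
             os3_high = 100 * vals[[2]]$ci_high,
             os5 = 100 * vals[[3]]$surv, os5_low = 100 * vals[[3]]$ci_low,
             os5_high = 100 * vals[[3]]$ci_high,
             suppressed = FALSE)
}

period_row <- function(cases, window, min_cases) {
  res <- tryCatch(period_survival(cases, window), error = function(e) NULL)
  if (is.null(res) || res$n_total < min_cases) {
    return(data.frame(n = if (is.null(res)) 0L else res$n_total,
                      os1 = NA_real_, os1_low = NA_real_, os1_high = NA_real_,
                      os3 = NA_real_, os3_low = NA_real_, os3_high = NA_real_,
                      os5 = NA_real_, os5_low = NA_real_, os5_high = NA_real_,
                      suppressed = TRUE))
  }
  vals <- lapply(c(1, 3, 5), function(t) os_at(res, t))
  data.frame(n = res$n_total,
             os1 = 100 * vals[[1]]$surv, os1_low = 100 * vals[[1]]$ci_low,
             os1_high = 100 * vals[[1]]$ci_high,
             os3 = 100 * vals[[2]]$surv, os3_low = 100 * vals[[2]]$ci_low,
             os3_high = 100 * vals[[2]]$ci_high,
             os5 = 100 * vals[[3]]$surv, os5_low = 100 * vals[[3]]$ci_low,
             os5_high = 100 * vals[[3]]$ci_high,
             suppressed = FALSE)
}

#' Cohort and period survival tables
#'
#' For each tumour group and 5-year diagnosis cohort, cohort Kaplan-Meier
#' overall survival at 1, 3 and 5 years with 95\% CIs; the most recent
#' calendar window uses the period approach. Cells based on fewer than
#' `min_cases` cases are suppressed (numeric fields `NA`, `suppressed`
#' flag set; rendered as "-" by [format_report_table()]).
#'
#' @param cases a `registry_cases` table (already cohort-filtered).
#' @param config a [run_config()].
#' @return data.frame, one row per group x cohort.
#' @export
run_cohort_tables <- function(cases, config = run_config()) {
  rows <- list()
  for (g in config$groups) {
    sel <- select_tumour_group(cases, g)
    for (co in config$cohorts) {
      sub <- sel[sel$diagnosis_year >= co[1] & sel$diagnosis_year <= co[2], ,
                 drop = FALSE]
      r <- km_row(followup_observations(sub), config$min_cases)
      r <- cbind(group = g$label, cohort = paste0(co[1], "-", co[2]), r)
      rows[[length(rows) + 1]] <- r
    }
    r <- period_row(sel, config$period, config$min_cases)
    r <- cbind(group = g$label,
               cohort = paste0(config$period$calendar_start, "-",
                               config$period$calendar_end, " (period)"), r)
    rows[[length(rows) + 1]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-group and sex survival tables with log-rank tests
#'
#' Restricted to the configured recent cohort (default 2009-2018). Age
#' groups are pooled with [pool_age_groups()] (infant split kept when both
#' `<1` and `1-4` reach `min_cases`); a log-rank p-value compares the
#' resulting age groups, and a second table compares the sexes.
#'
#' @param cases a `registry_cases` table.
#' @param config a [run_config()].
#' @return list with data.frames `age` (one row per group x age group,
#'   with `p_logrank` repeated per group) and `sex`.
#' @export
run_age_sex_tables <- function(cases, config = run_config()) {
  yr <- config$age_sex_cohort
  cohort <- cases[cases$diagnosis_year >= yr[1] & cases$diagnosis_year <= yr[2], ,
                  drop = FALSE]
  age_rows <- list()
  sex_rows <- list()
  for (g in config$groups) {
    sel <- select_tumour_group(cohort, g)
    obs <- followup_observations(sel)
    counts <- vapply(AGE_GROUPS, function(a) sum(obs$age_group == a), numeric(1))
    grouping <- pool_age_groups(counts, min_cases = config$min_cases,
                                direction_hint = g$direction_hint,
                                allow_infant_split = TRUE)
    obs$pooled <- map_age_group(obs$age_group, grouping)
    by_age <- split(obs, factor(obs$pooled, levels = grouping))
    nonempty <- by_age[vapply(by_age, nrow, integer(1)) > 0]
    p_age <- if (length(nonempty) >= 2) {
      logrank_test(nonempty, horizon = 5)$p_value
    } else NA_real_
    for (a in grouping) {
      sub <- obs[obs$pooled == a, , drop = FALSE]
      r <- km_row(sub, config$min_cases)
      age_rows[[length(age_rows) + 1]] <-
        cbind(group = g$label, age_group = a, r, p_logrank = p_age)
    }
    by_sex <- split(obs, obs$sex)
    by_sex <- by_sex[vapply(by_sex, nrow, integer(1)) > 0]
    p_sex <- if (length(by_sex) >= 2) logrank_test(by_sex, horizon = 5)$p_value
      else NA_real_
    for (s in names(by_sex)) {
      r <- km_row(by_sex[[s]], config$min_cases)
      sex_rows[[length(sex_rows) + 1]] <-
        cbind(group = g$label, sex = s, r, p_logrank = p_sex)
    }
  }
  list(age = do.call(rbind, c(age_rows, list(make.row.names = FALSE))),
       sex = do.call(rbind, c(sex_rows, list(make.row.names = FALSE))))
}

#' Fitted survival trends per tumour group
#'
#' For each tumour group: derives case-pool age weights (after pooling to a
#' grouping viable in every cohort), fits the BIC-selected Cox-joinpoint
#' model stratified by that grouping, computes the age-standardised fitted
#' 5-year survival series with its band and AACS bootstrap CI, and attaches
#' the observed annual cohort and period estimates (the black and grey dots
#' of registry trend figures). Groups whose strata cannot support a
#' stratified fit (a stratum without events) fall back to an unstratified
#' fit with a note.
#'
#' @param cases a `registry_cases` table.
#' @param config a [run_config()].
#' @return named list (per group label) of lists with `series`, `model`,
#'   `weights`, `dots` (data.frame year/type/os5), and `note`.
#' @export
run_trends <- function(cases, config = run_config()) {
  out <- list()
  for (g in config$groups) {
    sel <- select_tumour_group(cases, g)
    counts <- t(vapply(config$cohorts, function(co) {
      sub <- sel[sel$diagnosis_year >= co[1] & sel$diagnosis_year <= co[2], ]
      vapply(AGE_GROUPS, function(a) sum(sub$age_group == a), numeric(1))
    }, numeric(length(AGE_GROUPS))))
    colnames(counts) <- AGE_GROUPS
    grouping <- if (g$standardise) {
      pool_age_groups(counts, min_cases = config$min_cases,
                      direction_hint = g$direction_hint)
    } else "0-14"
    note <- NULL
    if (identical(grouping, "0-14")) {
      note <- "unstratified fit (no age standardisation)"
    }
    obs <- cox_observations(sel, grouping = grouping)
    weights <- derive_weights(sel, grouping)
    model <- tryCatch(
      select_joinpoints(obs, max_joinpoints = config$max_joinpoints,
                        min_segment = config$min_segment),
      error = function(e) NULL)
    if (is.null(model) && !identical(grouping, "0-14")) {
      note <- "stratified fit failed; fell back to unstratified"
      grouping <- "0-14"
      obs <- cox_observations(sel, grouping = grouping)
      weights <- derive_weights(sel, grouping)
      model <- select_joinpoints(obs, max_joinpoints = config$max_joinpoints,
                                 min_segment = config$min_segment)
    }
    series <- adjusted_s5_series(model, weights)
    boot <- bootstrap_aacs(obs, model$basis, weights,
                           B = config$bootstrap_reps, seed = config$seed)
    series$aacs_ci <- boot$ci
    series$aacs_median <- boot$median
    out[[g$label]] <- list(series = series, model = model, weights = weights,
                           dots = annual_dots(sel, config), note = note)
  }
  out
}

# Observed annual 5-year survival: cohort estimates for diagnosis years with
# complete follow-up, period estimates (single-year windows) for recent
# calendar years.
annual_dots <- function(cases, config) {
  last_complete <- config$period$calendar_end - 5L
  rows <- list()
  for (y in sort(unique(cases$diagnosis_year))) {
    sub <- cases[cases$diagnosis_year == y, , drop = FALSE]
    if (nrow(sub) < config$min_cases) next
    if (y <= last_complete) {
      curve <- kaplan_meier(followup_observations(sub), horizon = 5)
      rows[[length(rows) + 1]] <- data.frame(
        year = y, type = "cohort", os5 = 100 * os_at(curve, 5)$surv)
    }
  }
  for (y in (last_complete + 1L):config$period$calendar_end) {
    win <- period_window(y, y, horizon = 5)
    res <- tryCatch(period_survival(cases, win), error = function(e) NULL)
    if (!is.null(res) && res$n_total >= config$min_cases) {
      rows[[length(rows) + 1]] <- data.frame(
        year = y, type = "period", os5 = 100 * os_at(res, 5)$surv)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Render a report table with suppression markers
#'
#' Formats the numeric survival columns as `"est [low, high]"` strings and
#' renders suppressed cells as `"-"`, so suppressed estimates never leak
#' into any output artifact.
#'
#' @param table data.frame from [run_cohort_tables()] or
#'   [run_age_sex_tables()].
#' @param digits decimal places (default 1).
#' @return data.frame of character columns ready for CSV export.
#' @export
format_report_table <- function(table, digits = 1) {
  fmt <- function(e, lo, hi, suppressed) {
    ifelse(suppressed | is.na(e), "-",
           sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
                   e, lo, hi))
  }
  keep <- setdiff(names(table), c("os1", "os1_low", "os1_high", "os3",
                                  "os3_low", "os3_high", "os5", "os5_low",
                                  "os5_high", "suppressed"))
  out <- table[keep]
  out$os1 <- fmt(table$os1, table$os1_low, table$os1_high, table$suppressed)
  out$os3 <- fmt(table$os3, table$os3_low, table$os3_high, table$suppressed)
  out$os5 <- fmt(table$os5, table$os5_low, table$os5_high, table$suppressed)
  out
}

#' Run the full reporting pipeline and write outputs
#'
#' Cohort/period tables, age and sex tables, and per-group trend series,
#' written as CSV/JSON into `config$output_dir` together with a
#' machine-readable run manifest (seed, input checksum, settings).
#'
#' @param cases a `registry_cases` table.
#' @param config a [run_config()] with `output_dir` set.
#' @return invisibly, a list with all computed results and the manifest.
#' @export
run_report <- function(cases, config = run_config()) {
  dir <- config$output_dir
  if (is.null(dir)) stop("run_report needs config$output_dir")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  input_path <- file.path(dir, "input_cases.csv")
  write_registry(cases, input_path)
  cohort <- run_cohort_tables(cases, config)
  agesex <- run_age_sex_tables(cases, config)
  trends <- run_trends(cases, config)
  write.csv(format_report_table(cohort), file.path(dir, "cohort_tables.csv"),
            row.names = FALSE)
  write.csv(format_report_table(agesex$age), file.path(dir, "age_tables.csv"),
            row.names = FALSE)
  write.csv(format_report_table(agesex$sex), file.path(dir, "sex_tables.csv"),
            row.names = FALSE)
  trend_json <- lapply(trends, function(tr) {
    list(years = tr$series$years, s5 = tr$series$s5,
         band_low = tr$series$band_low, band_high = tr$series$band_high,
         extrapolated = tr$series$extrapolated,
         aacs = tr$series$aacs, aacs_ci = tr$series$aacs_ci,
         joinpoints = tr$model$basis$joinpoints,
         segment_slopes = coef_to_slopes(tr$model$beta),
         bic = tr$model$bic, note = tr$note,
         dots = tr$dots)
  })
  jsonlite::write_json(trend_json, file.path(dir, "trends.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    seed = config$seed,
    input_md5 = unname(tools::md5sum(input_path)),
    n_cases = nrow(cases),
    cohorts = config$cohorts,
    period = unclass(config$period),
    min_cases = config$min_cases,
    trend = list(max_joinpoints = config$max_joinpoints,
                 min_segment = config$min_segment,
                 bootstrap_reps = config$bootstrap_reps),
    groups = vapply(config$groups, function(g) g$label, character(1))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, age_sex = agesex, trends = trends,
                 manifest = manifest))
}
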