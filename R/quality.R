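# IARC-style data-quality indicators and the small descriptive statistics
# reported alongside them.

# ICCC labels counted as "unspecified" (NOS) in the IARC indicator, plus
# leukaemias (group I) with non-specific histology codes.
NOS_SUBGROUP_CODES <- c("IIe", "IIIf", "VIc", "VIIc", "VIIIe", "IXe",
                        "Xe", "XIf", "XIIb")
NOS_LEUKAEMIA_MORPHOLOGY <- c(8000L, 8800L, 9800L)

#' IARC quality indicators for a registry case table
#'
#' Computes the standard childhood-cancer registry quality indicators:
#'
#' * `mv_pct` — percentage of cases microscopically verified.
#' * `dco_pct` — percentage ascertained from death certificate only.
#'   Structurally 0 here: hospital-based registries of this kind do not
#'   register new cases from death certificates, and the case table holds
#'   no DCO flag. The field is kept for IARC-format parity.
#' * `nos_pct` — percentage of unspecified cases: ICCC labels IIe, IIIf,
#'   VIc, VIIc, VIIIe, IXe, Xe, XIf and XIIb, plus leukaemias with
#'   histology codes 8000, 8800 or 9800.
#' * `infant_pct` — percentage of all registered cases aged <1 year.
#' * `nonmalignant_cns_pct` — percentage of non-malignant cases among CNS
#'   tumours (diagnostic group III plus subgroup Xa).
#'
#' @param cases a non-empty `registry_cases` table.
#' @return a `quality_report` list with the five percentages.
#' @export
quality_indicators <- function(cases) {
  if (nrow(cases) == 0) stop("quality indicators are undefined on an empty case table")
  parsed <- iccc_parse(cases$iccc_code)
  n <- nrow(cases)
  nos <- cases$iccc_code %in% NOS_SUBGROUP_CODES |
    (parsed$group == "I" & cases$morphology %in% NOS_LEUKAEMIA_MORPHOLOGY)
  cns <- parsed$group == "III" | cases$iccc_code == "Xa"
  n_cns <- sum(cns)
  structure(list(
    mv_pct = 100 * sum(cases$microscopically_verified) / n,
    dco_pct = 0,
    nos_pct = 100 * sum(nos) / n,
    infant_pct = 100 * sum(cases$age_group == "<1") / n,
    nonmalignant_cns_pct =
      if (n_cns == 0) NA_real_
      else 100 * sum(cns & cases$behaviour == "non_malignant") / n_cns,
    n_cases = n,
    n_cns = n_cns
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, digits = 1, ...) {
  fmt <- function(v) if (is.na(v)) "-" else formatC(v, format = "f", digits = digits)
  cat("IARC quality indicators (", x$n_cases, " cases)\n", sep = "")
  cat(sprintf("  %-42s %s\n", "Microscopically verified cases (MV%)", fmt(x$mv_pct)))
  cat(sprintf("  %-42s %s\n", "Death-certificate-only cases (DCO%)",
              "- (not a registration source)"))
  cat(sprintf("  %-42s %s\n", "Unspecified cases (NOS%)", fmt(x$nos_pct)))
  cat(sprintf("  %-42s %s\n", "Cases aged <1 year (%)", fmt(x$infant_pct)))
  cat(sprintf("  %-42s %s\n", "Non-malignant CNS cases (%)",
              fmt(x$nonmalignant_cns_pct)))
  invisible(x)
}

#' Serialise a quality report to JSON
#'
#' @param x a `quality_report`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly if written to file.
#' @export
quality_report_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Descriptive case-mix proportions
#'
#' Percentages of haematological neoplasms (ICCC groups I-II), solid tumours
#' (all other groups), non-malignant CNS cases among CNS tumours, and second
#' or later primaries, each over the supplied case table.
#'
#' @param cases a non-empty `registry_cases` table.
#' @return list with counts (`n_*`) and percentages (`*_pct`).
#' @export
case_mix <- function(cases) {
  if (nrow(cases) == 0) stop("case mix is undefined on an empty case table")
  parsed <- iccc_parse(cases$iccc_code)
  n <- nrow(cases)
  haem <- parsed$group %in% c("I", "II")
  cns <- parsed$group == "III" | cases$iccc_code == "Xa"
  second <- cases$sequence_number >= 2L
  list(
    n_total = n,
    n_haematological = sum(haem),
    n_solid = sum(!haem),
    n_cns = sum(cns),
    n_nonmalignant_cns = sum(cns & cases$behaviour == "non_malignant"),
    n_second_tumours = sum(second),
    haematological_pct = 100 * sum(haem) / n,
    solid_pct = 100 * sum(!haem) / n,
    nonmalignant_cns_pct = if (sum(cns) == 0) NA_real_
      else 100 * sum(cns & cases$behaviour == "non_malignant") / sum(cns),
    second_tumour_pct = 100 * sum(second) / n
  )
}

#' Linear trend in the annual proportion of non-malignant CNS cases
#'
#' Restricts to CNS tumours (group III plus subgroup Xa), computes the
#' annual proportion of non-malignant cases, and fits an ordinary
#' least-squares line of proportion on diagnosis year.
#'
#' @param cases a `registry_cases` table containing CNS cases in at least
#'   three distinct diagnosis years.
#' @return list with `slope` (per year), `se`, `p_value` (two-sided),
#'   and the annual `data` used for the fit.
#' @export
nonmalignant_cns_trend_test <- function(cases) {
  parsed <- iccc_parse(cases$iccc_code)
  cns <- cases[parsed$group == "III" | cases$iccc_code == "Xa", , drop = FALSE]
  if (nrow(cns) == 0) stop("no CNS cases; trend test needs >= 3 annual points")
  annual <- aggregate(
    cbind(prop = cns$behaviour == "non_malignant"),
    by = list(year = cns$diagnosis_year), FUN = mean
  )
  if (nrow(annual) < 3) {
    stop("trend test needs >= 3 diagnosis years with CNS cases, got ",
         nrow(annual))
  }
  fit <- lm(prop ~ year, data = annual)
  # summary() warns on a zero-residual fit; that case is handled explicitly
  smry <- suppressWarnings(summary(fit))
  s <- smry$coefficients
  slope <- unname(s["year", "Estimate"])
  p <- unname(s["year", "Pr(>|t|)"])
  # an (up to rounding) perfect fit has no residual variance: a flat line is
  # then exactly consistent (p = 1), a non-zero slope exactly inconsistent
  scale <- max(mean(abs(annual$prop)), .Machine$double.eps)
  if (is.nan(p) || smry$sigma <= 1e-10 * scale) {
    p <- if (abs(slope) <= 1e-10 * scale) 1 else 0
  }
  list(slope = slope,
       se = unname(s["year", "Std. Error"]),
       p_value = p,
       data = annual)
}
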