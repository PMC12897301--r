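# Case-pool age standardisation: weight derivation, adjacent-group pooling
# for small cohorts, weighted combination of age-specific estimates, and
# small-cell suppression.

#' Age-group weights
#'
#' @param grouping ordered character vector of (possibly pooled) age-group
#'   labels (see [age_group_labels()]).
#' @param weights numeric proportions, one per group, summing to 1.
#' @return an `age_weights` object.
#' @export
age_weights <- function(grouping, weights) {
  stopifnot(length(grouping) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (!all(grouping %in% age_group_labels(pooled = TRUE))) {
    stop("unknown age-group label(s): ",
         paste(setdiff(grouping, age_group_labels(pooled = TRUE)), collapse = ", "))
  }
  structure(list(grouping = grouping, weights = as.numeric(weights)),
            class = "age_weights")
}

#' @export
print.age_weights <- function(x, ...) {
  cat("Case-pool age weights:\n")
  for (i in seq_along(x$grouping)) {
    cat(sprintf("  %-6s %.4f\n", x$grouping[i], x$weights[i]))
  }
  invisible(x)
}

#' Derive age weights from a case pool
#'
#' Case-pool standardisation: the weight of each (possibly pooled) age group
#' is its share of the full case pool, so standardised estimates read on the
#' scale of observed all-ages survival.
#'
#' @param case_pool a non-empty `registry_cases` table (typically the full
#'   1999-2021 pool for the tumour in question).
#' @param grouping target grouping, e.g. from [pool_age_groups()].
#' @return an [age_weights()] object.
#' @export
derive_weights <- function(case_pool, grouping = c("0-4", "5-9", "10-14")) {
  if (nrow(case_pool) == 0) stop("cannot derive weights from an empty case pool")
  mapped <- map_age_group(as.character(case_pool$age_group), grouping)
  counts <- vapply(grouping, function(g) sum(mapped == g), numeric(1))
  age_weights(grouping, counts / sum(counts))
}

#' Pool adjacent age groups for small cohorts
#'
#' Returns the coarsest-necessary grouping for age standardisation. The
#' default grouping is `{0-4, 5-9, 10-14}`, with the infant group `<1` split
#' out only when both `<1` and `1-4` reach `min_cases` in every cohort. If
#' any group in any cohort falls below `min_cases`, adjacent groups are
#' merged to two (`{0-9, 10-14}` for tumours typically diagnosed at older
#' ages, `{0-4, 5-14}` for young-heavy tumours; with no hint, the merge that
#' yields the larger combined deficient-side count). If a two-group split is
#' still deficient, everything collapses to `0-14` (no standardisation).
#'
#' @param counts_per_cohort numeric matrix of case counts, one row per
#'   cohort, columns named by the four age groups `<1`, `1-4`, `5-9`,
#'   `10-14` (a single named vector is treated as one cohort).
#' @param min_cases minimum cases per group per cohort (default 15).
#' @param direction_hint `"old-heavy"`, `"young-heavy"` or `"none"`.
#' @param allow_infant_split if `TRUE` (used for age-specific reporting
#'   tables rather than standardisation), keep `<1` and `1-4` separate when
#'   both reach `min_cases` in every cohort.
#' @return character vector: the selected grouping.
#' @export
pool_age_groups <- function(counts_per_cohort, min_cases = 15,
                            direction_hint = c("none", "old-heavy", "young-heavy"),
                            allow_infant_split = FALSE) {
  direction_hint <- match.arg(direction_hint)
  if (is.null(dim(counts_per_cohort))) {
    counts_per_cohort <- matrix(counts_per_cohort, nrow = 1,
                                dimnames = list(NULL, names(counts_per_cohort)))
  }
  if (!all(AGE_GROUPS %in% colnames(counts_per_cohort))) {
    stop("counts need columns ", paste(AGE_GROUPS, collapse = ", "))
  }
  cc <- counts_per_cohort[, AGE_GROUPS, drop = FALSE]
  if (any(cc < 0)) stop("negative case counts")
  ok <- function(grouping) {
    pooled <- vapply(grouping, function(g) {
      members <- AGE_GROUPS[map_age_group(AGE_GROUPS, grouping) == g]
      rowSums(cc[, members, drop = FALSE])
    }, numeric(nrow(cc)))
    all(pooled >= min_cases)
  }
  if (allow_infant_split && ok(AGE_GROUPS)) return(AGE_GROUPS)
  three <- c("0-4", "5-9", "10-14")
  if (ok(three)) return(three)
  old <- c("0-9", "10-14")
  young <- c("0-4", "5-14")
  two <- switch(direction_hint,
    "old-heavy" = old,
    "young-heavy" = young,
    "none" = {
      # merge the deficient middle toward the neighbour giving the larger
      # combined count
      if (sum(cc[, c("<1", "1-4", "5-9")]) >= sum(cc[, c("5-9", "10-14")]))
        old else young
    })
  if (ok(two)) return(two)
  "0-14"
}

#' Age-standardised estimate from per-group estimates
#'
#' Weighted combination `sum(w_a * S_a)` with standard error
#' `sqrt(sum(w_a^2 * se_a^2))` under independence of the age strata.
#'
#' @param estimates data.frame with columns `group`, `value` (survival
#'   proportion in \[0, 1\]), `se`, and optionally `n` (case count).
#' @param weights an [age_weights()] whose grouping matches
#'   `estimates$group` exactly (any order).
#' @return a `standardised_estimate` list: `value`, `se`, `components`,
#'   `suppressed` (FALSE here; see [suppress_small()]).
#' @export
standardise <- function(estimates, weights) {
  stopifnot(inherits(weights, "age_weights"))
  if (!setequal(estimates$group, weights$grouping) ||
      nrow(estimates) != length(weights$grouping)) {
    stop("estimates and weights cover different age groupings")
  }
  estimates <- estimates[match(weights$grouping, estimates$group), , drop = FALSE]
  value <- sum(weights$weights * estimates$value)
  se <- sqrt(sum(weights$weights^2 * estimates$se^2))
  structure(list(value = value, se = se,
                 components = cbind(estimates, weight = weights$weights),
                 suppressed = FALSE),
            class = "standardised_estimate")
}

#' Suppress estimates based on too few cases
#'
#' Registry reporting rule: estimates based on fewer than `min_cases` cases
#' are withheld. The boundary is strict: exactly `min_cases` cases are
#' reported.
#'
#' @param estimate a `standardised_estimate`, a `survival_curve` summary, or
#'   any value to be reported.
#' @param n number of contributing cases.
#' @param min_cases suppression threshold (default 15).
#' @return the estimate unchanged, or a `suppressed` marker object.
#' @export
suppress_small <- function(estimate, n, min_cases = 15) {
  stopifnot(n >= 0)
  if (n < min_cases) {
    return(structure(list(value = NULL, n = n, suppressed = TRUE),
                     class = "suppressed"))
  }
  estimate
}

#' Test for a suppression marker
#' @param x object returned by [suppress_small()].
#' @return `TRUE` if `x` is a suppression marker.
#' @export
is_suppressed <- function(x) {
  inherits(x, "suppressed") ||
    (is.list(x) && isTRUE(x$suppressed))
}

#' @export
print.standardised_estimate <- function(x, ...) {
  cat(sprintf("Age-standardised estimate: %.1f%% (se %.2f pp)\n",
              100 * x$value, 100 * x$se))
  invisible(x)
}

#' Serialise age weights to JSON
#' @param weights an [age_weights()].
#' @param path optional output file.
#' @return JSON string, invisibly when written to file.
#' @export
age_weights_json <- function(weights, path = NULL) {
  json <- jsonlite::toJSON(list(grouping = weights$grouping,
                                weights = weights$weights), digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
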