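#' Construct a registry case table
#'
#' A `registry_cases` object is a `data.frame` with one row per registered
#' tumour and a fixed set of typed columns: `case_id`, `diagnosis_date`
#' (`Date`), `diagnosis_year` (integer), `age_group` (factor, see
#' [age_group_labels()]), `sex` (`"female"`/`"male"`), `iccc_code`
#' (diagnostic group/subgroup label such as `"Ia"` or `"IIIb"`), `behaviour`
#' (`"malignant"`/`"non_malignant"`), `morphology` (4-digit histology code),
#' `microscopically_verified` (logical), `sequence_number` (1 = first
#' primary), `vital_status` (`"alive"`/`"dead"`/`"lost"`) and
#' `followup_end_date` (`Date` of death, last contact or administrative
#' closure).
#'
#' @param df data.frame holding the columns above (coercible types accepted).
#' @return a validated `registry_cases` data.frame.
#' @export
registry_cases <- function(df) {
  required <- c("case_id", "diagnosis_date", "diagnosis_year", "age_group",
                "sex", "iccc_code", "behaviour", "morphology",
                "microscopically_verified", "sequence_number",
                "vital_status", "followup_end_date")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing registry column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$case_id <- as.character(df$case_id)
  df$diagnosis_date <- as.Date(df$diagnosis_date)
  df$diagnosis_year <- as.integer(df$diagnosis_year)
  df$age_group <- factor(as.character(df$age_group), levels = AGE_GROUPS)
  df$sex <- factor(as.character(df$sex), levels = c("female", "male"))
  df$iccc_code <- as.character(df$iccc_code)
  df$behaviour <- factor(as.character(df$behaviour),
                         levels = c("malignant", "non_malignant"))
  df$morphology <- as.integer(df$morphology)
  df$microscopically_verified <- as.logical(df$microscopically_verified)
  df$sequence_number <- as.integer(df$sequence_number)
  df$vital_status <- factor(as.character(df$vital_status),
                            levels = c("alive", "dead", "lost"))
  df$followup_end_date <- as.Date(df$followup_end_date)
  problems <- validate_case_rows(df)
  if (any(nzchar(problems))) {
    bad <- which(nzchar(problems))
    stop("invalid case record(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": ", problems[bad[1]])
  }
  rownames(df) <- NULL
  class(df) <- c("registry_cases", "data.frame")
  df
}

# One reason string per row; "" when the row is a valid CaseRecord.
validate_case_rows <- function(df) {
  reason <- character(nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & !nzchar(reason)] <<- msg
  }
  flag(is.na(df$diagnosis_date), "missing or unparseable diagnosis_date")
  flag(is.na(df$followup_end_date), "missing or unparseable followup_end_date")
  flag(df$followup_end_date < df$diagnosis_date,
       "followup_end_date precedes diagnosis_date")
  flag(is.na(df$age_group), "age_group outside <1/1-4/5-9/10-14 (age >= 15?)")
  flag(is.na(df$sex), "invalid sex")
  flag(is.na(df$behaviour), "invalid behaviour")
  flag(is.na(df$vital_status), "invalid vital_status")
  flag(is.na(df$sequence_number) | df$sequence_number < 1L,
       "sequence_number must be a positive integer")
  flag(is.na(df$diagnosis_year), "missing diagnosis_year")
  ok_year <- !is.na(df$diagnosis_year) & !is.na(df$diagnosis_date)
  flag(ok_year & df$diagnosis_year != as.integer(format(df$diagnosis_date, "%Y")),
       "diagnosis_year inconsistent with diagnosis_date")
  reason
}

#' @export
print.registry_cases <- function(x, ...) {
  span <- if (nrow(x) > 0) {
    paste(" diagnosis years", min(x$diagnosis_year), "-", max(x$diagnosis_year))
  } else ""
  cat("Registry case table:", nrow(x), "tumours,", span, "\n")
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat("  (", nrow(rej), "input rows rejected on read)\n")
  }
  NextMethod()
}

#' Column-mapping dialect for registry tables
#'
#' Describes how a delimited text file maps onto the registry columns:
#' the separator and a named mapping `field -> column name in the file`.
#' Fields not mentioned are assumed to use their canonical names.
#'
#' @param sep field separator (default `","`).
#' @param columns named character vector or list, e.g.
#'   `c(case_id = "id", diagnosis_date = "date_dx")`.
#' @return a `registry_dialect` list.
#' @export
registry_dialect <- function(sep = ",", columns = character()) {
  canonical <- c("case_id", "diagnosis_date", "diagnosis_year", "age_group",
                 "sex", "iccc_code", "behaviour", "morphology",
                 "microscopically_verified", "sequence_number",
                 "vital_status", "followup_end_date")
  columns <- unlist(columns)
  if (length(columns) > 0 && !all(names(columns) %in% canonical)) {
    stop("unknown field(s) in dialect mapping: ",
         paste(setdiff(names(columns), canonical), collapse = ", "))
  }
  map <- setNames(canonical, canonical)
  map[names(columns)] <- columns
  structure(list(sep = sep, columns = map), class = "registry_dialect")
}

#' Read a registry dialect from a YAML or JSON config file
#'
#' The config may hold `sep` and a `columns` mapping.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `registry_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  registry_dialect(sep = cfg$sep %||% ",", columns = cfg$columns %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a registry case table from delimited text
#'
#' Each well-formed row becomes a case record; rows violating record
#' invariants (e.g. follow-up ending before diagnosis) are rejected, not
#' fatal, and reported with their row number and reason in the
#' `rejections` attribute.
#'
#' @param path file path.
#' @param dialect a [registry_dialect()]; default assumes canonical headers
#'   and comma separation.
#' @return a `registry_cases` table; `attr(, "rejections")` is a data.frame
#'   with columns `row` (1-based data row in the file) and `reason`.
#' @seealso [write_registry()], [n_rejected()]
#' @export
read_registry <- function(path, dialect = registry_dialect()) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing) > 0) {
    stop("registry file lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- setNames(raw[unname(dialect$columns)], names(dialect$columns))
  df$diagnosis_date <- as.Date(df$diagnosis_date)
  df$followup_end_date <- as.Date(df$followup_end_date)
  df$diagnosis_year <- suppressWarnings(as.integer(df$diagnosis_year))
  df$morphology <- suppressWarnings(as.integer(df$morphology))
  df$sequence_number <- suppressWarnings(as.integer(df$sequence_number))
  df$microscopically_verified <-
    tolower(df$microscopically_verified) %in% c("true", "t", "1", "yes")
  df$age_group <- factor(df$age_group, levels = AGE_GROUPS)
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$behaviour <- factor(df$behaviour, levels = c("malignant", "non_malignant"))
  df$vital_status <- factor(df$vital_status, levels = c("alive", "dead", "lost"))
  reason <- validate_case_rows(df)
  keep <- !nzchar(reason)
  rejections <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  cases <- registry_cases(df[keep, , drop = FALSE])
  attr(cases, "rejections") <- rejections
  cases
}

#' Number of rows rejected when a registry table was read
#'
#' @param cases a `registry_cases` table returned by [read_registry()].
#' @return integer count of rejected input rows.
#' @export
n_rejected <- function(cases) {
  rej <- attr(cases, "rejections")
  if (is.null(rej)) 0L else nrow(rej)
}

#' Write a registry case table to delimited text
#'
#' Inverse of [read_registry()]: a file written here and re-read with the
#' same dialect yields an identical record collection.
#'
#' @param cases a `registry_cases` table.
#' @param path output file path.
#' @param dialect a [registry_dialect()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(cases, path, dialect = registry_dialect()) {
  out <- as.data.frame(cases)
  out$diagnosis_date <- format(out$diagnosis_date, "%Y-%m-%d")
  out$followup_end_date <- format(out$followup_end_date, "%Y-%m-%d")
  out$microscopically_verified <- ifelse(out$microscopically_verified,
                                         "true", "false")
  names(out) <- unname(dialect$columns[names(out)])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split an ICCC code into diagnostic group and subgroup
#'
#' `"IIIb"` has group `"III"` and subgroup `"b"`; a bare group label such as
#' `"V"` has an empty subgroup.
#'
#' @param code character vector of ICCC group/subgroup labels.
#' @return data.frame with columns `group` and `subgroup`.
#' @export
iccc_parse <- function(code) {
  # longest roman numeral first so e.g. "IIIb" is not split as "I" + "IIb"
  pat <- "^(XII|XI|IX|X|VIII|VII|VI|IV|V|III|II|I)([a-z]*)$"
  ok <- grepl(pat, code)
  if (!all(ok)) {
    stop("unparseable ICCC code(s): ", paste(unique(code[!ok]), collapse = ", "))
  }
  data.frame(group = sub(pat, "\\1", code),
             subgroup = sub(pat, "\\2", code),
             stringsAsFactors = FALSE)
}

#' Cohort filter settings
#'
#' Defaults implement the study-population rules of national paediatric
#' registry analyses: exclude myelodysplastic/myeloproliferative diseases
#' (ICCC `Id`) and miscellaneous lymphoreticular neoplasms (`IId`), and keep
#' diagnosis years within the registration window.
#'
#' @param exclude_codes ICCC codes to drop.
#' @param year_range inclusive diagnosis-year window.
#' @return a `cohort_filter` list.
#' @export
cohort_filter <- function(exclude_codes = c("Id", "IId"),
                          year_range = c(1999L, 2021L)) {
  structure(list(exclude_codes = exclude_codes,
                 year_range = as.integer(year_range)),
            class = "cohort_filter")
}

#' Apply cohort inclusion filters
#'
#' Drops excluded ICCC codes and out-of-window diagnosis years. Idempotent;
#' the input is not modified.
#'
#' @param cases a `registry_cases` table.
#' @param config a [cohort_filter()].
#' @return filtered `registry_cases` (possibly empty).
#' @export
apply_cohort_filters <- function(cases, config = cohort_filter()) {
  keep <- !(cases$iccc_code %in% config$exclude_codes) &
    cases$diagnosis_year >= config$year_range[1] &
    cases$diagnosis_year <= config$year_range[2]
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- NULL
  class(out) <- c("registry_cases", "data.frame")
  out
}
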