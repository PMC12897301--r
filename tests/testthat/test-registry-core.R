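test_that("registry read/write round-trips all fields and reports rejections", {
  df <- rbind(
    make_cases(3, diagnosis_year = 2001, vital_status = "dead",
               followup_years = 1.2),
    make_cases(2, diagnosis_year = 2015, iccc_code = "IIIb",
               behaviour = "non_malignant", age_group = "10-14", sex = "female")
  )
  df$case_id <- sprintf("R%03d", seq_len(nrow(df)))
  cases <- registry_cases(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(cases, path)
  back <- read_registry(path)
  expect_equal(n_rejected(back), 0L)
  attr(back, "rejections") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(cases))

  # a custom dialect maps renamed columns
  dialect <- registry_dialect(sep = ";", columns = c(case_id = "id",
                                                     diagnosis_date = "dx_date"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(cases, path2, dialect)
  expect_match(readLines(path2, n = 1), "^id;dx_date")
  back2 <- read_registry(path2, dialect)
  attr(back2, "rejections") <- NULL
  expect_equal(as.data.frame(back2), as.data.frame(cases))
})

test_that("rows violating record invariants are rejected with reasons, not fatal", {
  df <- make_cases(3)
  df$followup_end_date[2] <- df$diagnosis_date[2] - 10  # follow-up before diagnosis
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(lapply(df, as.character)), path, row.names = FALSE,
            quote = FALSE)
  cases <- read_registry(path)
  expect_equal(nrow(cases), 2L)
  expect_equal(n_rejected(cases), 1L)
  rej <- attr(cases, "rejections")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "precedes")
  # a missing mandatory column is a configuration error, not a rejection
  df2 <- df[setdiff(names(df), "vital_status")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_registry(path2), "vital_status")
})

test_that("cohort filters drop excluded codes and out-of-window years, idempotently", {
  df <- rbind(make_cases(1, iccc_code = "Id"),
              make_cases(1, iccc_code = "Ia"),
              make_cases(1, iccc_code = "IId"),
              make_cases(1, iccc_code = "IIa", diagnosis_year = 1998),
              make_cases(1, iccc_code = "IIa", diagnosis_year = 2022))
  df$case_id <- sprintf("F%02d", 1:5)
  cases <- registry_cases(df)
  out <- apply_cohort_filters(cases)
  expect_equal(out$iccc_code, "Ia")
  expect_equal(nrow(cases), 5L)  # input unmodified
  expect_identical(as.data.frame(apply_cohort_filters(out)),
                   as.data.frame(out))  # idempotent
  empty <- apply_cohort_filters(cases[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("ICCC codes parse into group and subgroup", {
  p <- iccc_parse(c("Ia", "IIIb", "X", "XIf", "IVa", "IXe", "XIIb"))
  expect_equal(p$group, c("I", "III", "X", "XI", "IV", "IX", "XII"))
  expect_equal(p$subgroup, c("a", "b", "", "f", "a", "e", "b"))
  expect_error(iccc_parse("XIII"), "unparseable")
})

test_that("quality indicators recompute from brute-force counting", {
  # 95 cases of which 2 are IIe and 3 are leukaemias with morphology 9800,
  # among 5 others -> NOS 5/100 of the 100-case table below
  df <- rbind(make_cases(90, iccc_code = "Ia", morphology = 9835),
              make_cases(2, iccc_code = "IIe", morphology = 9590),
              make_cases(3, iccc_code = "Ia", morphology = 9800),
              make_cases(5, iccc_code = "IVa", morphology = 9500,
                         age_group = "<1", mv = FALSE))
  df$case_id <- sprintf("Q%03d", seq_len(nrow(df)))
  q <- quality_indicators(registry_cases(df))
  expect_equal(q$nos_pct, 5)
  expect_equal(q$mv_pct, 95)
  expect_equal(q$infant_pct, 5)
  expect_equal(q$dco_pct, 0)

  # all-verified edge
  q2 <- quality_indicators(registry_cases(make_cases(10)))
  expect_equal(q2$mv_pct, 100)
  expect_error(quality_indicators(registry_cases(make_cases(1)[0, , drop = FALSE])),
               "empty")
})

test_that("non-malignant CNS share counts group III plus subgroup Xa only", {
  df <- rbind(make_cases(30, iccc_code = "IIIb", behaviour = "non_malignant"),
              make_cases(50, iccc_code = "IIIc"),
              make_cases(10, iccc_code = "Xa", behaviour = "non_malignant"),
              make_cases(10, iccc_code = "Xc"),   # gonadal GCT: not CNS
              make_cases(100, iccc_code = "Ia"))
  df$case_id <- sprintf("C%03d", seq_len(nrow(df)))
  q <- quality_indicators(registry_cases(df))
  expect_equal(q$n_cns, 90)
  expect_equal(q$nonmalignant_cns_pct, 100 * 40 / 90)
  cm <- case_mix(registry_cases(df))
  expect_equal(cm$haematological_pct, 50)
  expect_equal(cm$solid_pct, 50)
})

test_that("CNS proportion trend test recovers flat, exact and noisy slopes", {
  flat <- do.call(rbind, lapply(2000:2009, function(y) {
    rbind(make_cases(7, diagnosis_year = y, iccc_code = "IIIb",
                     behaviour = "non_malignant"),
          make_cases(14, diagnosis_year = y, iccc_code = "IIIb"),
          make_cases(9, diagnosis_year = y, iccc_code = "IIIa"))
  }))
  flat$case_id <- sprintf("N%04d", seq_len(nrow(flat)))
  res <- nonmalignant_cns_trend_test(registry_cases(flat))
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.99)

  # proportions exactly linear in year: 0.10, 0.15, ..., recovered exactly
  lin <- do.call(rbind, lapply(0:9, function(i) {
    y <- 2000 + i
    nm <- 2 + i
    rbind(make_cases(nm, diagnosis_year = y, iccc_code = "IIIb",
                     behaviour = "non_malignant"),
          make_cases(20 - nm, diagnosis_year = y, iccc_code = "IIIb"))
  }))
  lin$case_id <- sprintf("L%04d", seq_len(nrow(lin)))
  res2 <- nonmalignant_cns_trend_test(registry_cases(lin))
  expect_equal(res2$slope, 0.05, tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-10)

  # simulated binomial proportions with known slope: estimate within 3 SE
  set.seed(11)
  truth <- 0.002
  sim <- do.call(rbind, lapply(1999:2021, function(y) {
    p <- 0.30 + truth * (y - 1999)
    nm <- rbinom(1, 200, p)
    rbind(make_cases(max(nm, 1), diagnosis_year = y, iccc_code = "IIIb",
                     behaviour = "non_malignant"),
          make_cases(200 - max(nm, 1), diagnosis_year = y, iccc_code = "IIIb"))
  }))
  sim$case_id <- sprintf("S%05d", seq_len(nrow(sim)))
  res3 <- nonmalignant_cns_trend_test(registry_cases(sim))
  expect_lt(abs(res3$slope - truth), 3 * res3$se)

  expect_error(nonmalignant_cns_trend_test(
    registry_cases(make_cases(5, iccc_code = "IIIb"))), ">= 3")
})

test_that("the packaged example extract reads with its dialect config", {
  csv <- system.file("extdata", "example_registry.csv", package = "registrend")
  dia <- system.file("extdata", "example_dialect.yaml", package = "registrend")
  dialect <- read_dialect(dia)
  cases <- read_registry(csv, dialect)
  expect_gt(nrow(cases), 10)
  expect_equal(n_rejected(cases), 0L)
  expect_s3_class(cases, "registry_cases")
})
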