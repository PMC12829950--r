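write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("parse_raw coerces dirty tokens and counts them per column", {
  gen <- toy_cohort(n = 10, seed = 1)
  raw <- as.data.frame(lapply(gen$cohort, as.character))
  names(raw) <- names(gen$cohort)
  raw$eGFR[3] <- "/"
  raw$BNP[5] <- "#DIV/0!"
  raw$PSD[7] <- "   "
  p <- parse_raw(write_cohort_csv(raw))
  expect_true(is.na(p$table$eGFR[3]))
  expect_true(is.na(p$table$BNP[5]))
  expect_true(is.na(p$table$PSD[7]))
  expect_equal(p$report$coerced_cells$eGFR[["/"]], 1)
  expect_equal(p$report$coerced_cells$BNP[["#DIV/0!"]], 1)
  expect_equal(p$table$age, gen$cohort$age)
})

test_that("a clean file yields an all-zero cleaning report", {
  gen <- toy_cohort(n = 15, seed = 2)
  p <- parse_raw(write_cohort_csv(gen$cohort))
  expect_length(p$report$coerced_cells, 0)
  expect_equal(p$report$n_rows_in, 15)
  expect_equal(p$table$GWW, gen$cohort$GWW)
})

test_that("parse_raw round-trips inject_dirty's recorded positions", {
  gen <- toy_cohort(n = 200, seed = 3)
  sp <- synthetic_spec(n_patients = 200, seed = 3, missing_rate = 0.1)
  dj <- inject_dirty(gen$cohort, sp)
  p <- parse_raw(write_cohort_csv(dj$raw))
  coerced_total <- sum(unlist(p$report$coerced_cells))
  expect_equal(coerced_total, nrow(dj$positions))
  for (i in seq_len(nrow(dj$positions))) {
    expect_true(is.na(p$table[dj$positions$row[i], dj$positions$column[i]]))
  }
})

test_that("parse_raw fails on unknown headers and unmappable categoricals", {
  gen <- toy_cohort(n = 5, seed = 4)
  bad <- gen$cohort
  names(bad)[names(bad) == "PSD"] <- "psd_ms"
  expect_error(parse_raw(write_cohort_csv(bad)), "psd_ms")

  bad2 <- as.data.frame(lapply(gen$cohort, as.character))
  names(bad2) <- names(gen$cohort)
  bad2$sex[2] <- "unknown"
  expect_error(parse_raw(write_cohort_csv(bad2)), "sex")
})

test_that("parse_raw is idempotent under serialize/parse", {
  gen <- toy_cohort(n = 50, seed = 5)
  sp <- synthetic_spec(n_patients = 50, seed = 5, missing_rate = 0.05)
  dj <- inject_dirty(gen$cohort, sp)
  p1 <- parse_raw(write_cohort_csv(dj$raw))
  p2 <- parse_raw(write_cohort_csv(p1$table))
  expect_equal(p2$table, p1$table, ignore_attr = TRUE)
})

test_that("impute fills medians and modes without touching observed values", {
  tbl <- data.frame(eGFR = c(1, 2, NA, 4), HTN = c(0, 0, 1, NA))
  out <- impute(tbl)
  expect_equal(out$table$eGFR, c(1, 2, 2, 4))   # median of {1,2,4}
  expect_equal(out$table$HTN, c(0, 0, 1, 0))    # mode, tie -> smaller code
  expect_equal(out$report$imputed_cells$eGFR, 1)

  # even count: mean of the two central order statistics
  tbl2 <- data.frame(BNP = c(10, 20, 30, 40, NA))
  expect_equal(impute(tbl2)$table$BNP[5], 25)

  # mode tie broken to the smaller code
  tbl3 <- data.frame(DM = c(0, 1, NA))
  expect_equal(impute(tbl3)$table$DM[3], 0)

  # no missing anywhere: identity
  gen <- toy_cohort(n = 30, seed = 6)
  expect_identical(impute(gen$cohort)$table, gen$cohort)

  expect_error(impute(data.frame(PSD = c(NA_real_, NA_real_))), "entirely missing")
})

test_that("imputation never changes an observed value (property)", {
  gen <- toy_cohort(n = 80, seed = 7)
  set.seed(7)
  tbl <- gen$cohort
  for (cn in c("eGFR", "BNP", "PSD", "HTN")) {
    tbl[[cn]][sample.int(80, 10)] <- NA
  }
  out <- impute(tbl)$table
  for (cn in names(tbl)) {
    obs <- !is.na(tbl[[cn]])
    expect_identical(out[[cn]][obs], tbl[[cn]][obs])
  }
})

test_that("complete_case_filter keeps exactly the fully observed rows", {
  gen <- toy_cohort(n = 5, seed = 8)
  tbl <- gen$cohort
  tbl$GWW[c(2, 4)] <- NA
  f <- complete_case_filter(tbl)
  expect_equal(nrow(f$table), 3)
  expect_equal(f$report$dropped_rows$patient_id, tbl$patient_id[c(2, 4)])
  expect_match(f$report$dropped_rows$reason[1], "GWW")

  f2 <- complete_case_filter(gen$cohort)
  expect_identical(f2$table, gen$cohort)

  tbl$GWW <- NA_real_
  expect_error(complete_case_filter(tbl), "every row")
  expect_error(complete_case_filter(gen$cohort, c("nope")), "nope")
})

test_that("the tuned 150 -> 84 complete-case flow reproduces n = 84", {
  gen <- generate_cohort(synthetic_spec(n_patients = 150, seed = 42))
  dj <- dirty_exact_rows(gen$cohort, n_complete_target = 84, seed = 42)
  p <- parse_raw(write_cohort_csv(dj$raw))
  f <- complete_case_filter(p$table)
  expect_equal(f$report$n_rows_out, 84)
  expect_equal(nrow(f$table), 84)

  # filter-then-impute leaves zero missing in required columns
  q <- ingest_qc(write_cohort_csv(dj$raw))
  req <- c(baseline_columns(), outcome_columns())
  expect_false(anyNA(q$table[, req]))
  expect_equal(nrow(q$table), 84)
})

test_that("zscore standardizes exactly and inverts", {
  # with the documented n-1 denominator, {2,4} has sd sqrt(2), so the
  # z-scores are +/- 1/sqrt(2)
  tbl <- data.frame(PSD = c(2, 4))
  z <- zscore(tbl, "PSD")
  expect_equal(z$table$PSD, c(-1, 1) / sqrt(2))
  expect_equal(z$sds[["PSD"]], sqrt(2))

  gen <- toy_cohort(n = 40, seed = 9)
  z2 <- zscore(gen$cohort, c("age", "PSD"))
  expect_lt(abs(mean(z2$table$PSD)), 1e-10)
  expect_equal(sd(z2$table$age), 1, tolerance = 1e-10)
  back <- z2$table$PSD * z2$sds[["PSD"]] + z2$means[["PSD"]]
  expect_equal(back, gen$cohort$PSD, tolerance = 1e-10)

  const <- data.frame(RWT = rep(0.5, 4))
  expect_error(zscore(const, "RWT"), "RWT")
})
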