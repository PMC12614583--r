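make_panel <- function(values, years = seq_along(values) + 1999,
                       strata = "Total", sizes = 1000L) {
  staforecast:::new_state_panel(data.frame(
    year = years, stratum = strata, value = values,
    sample_size = sizes, value_missing = is.na(values),
    stringsAsFactors = FALSE), "XX")
}

test_that("CSV reader enforces the required columns and flags blanks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "YearStart,LocationAbbr,Data_Value,Sample_Size,Stratification1",
    "2011,AK,29.1,1200,Total",
    "2012,AK,,1100,Total",
    "2013,AK,30.2,1300,Total"), path)
  p <- read_panel_csv(path)
  expect_equal(nrow(p), 3L)
  expect_equal(sum(p$value_missing), 1L)
  expect_true(is.na(p$value[p$year == 2012]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("YearStart,LocationAbbr,Sample_Size,Stratification1",
               "2011,AK,1200,Total"), bad)
  expect_error(read_panel_csv(bad), "Data_Value")

  nn <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "YearStart,LocationAbbr,Data_Value,Sample_Size,Stratification1",
    "2011,AK,oops,1200,Total"), nn)
  expect_error(read_panel_csv(nn), "line 2")
})

test_that("mean/mode imputation fills cells and counts them", {
  p <- make_panel(c(1, NA, 3))
  out <- impute_missing(p)
  expect_equal(out$panel$value, c(1, 2, 3))
  expect_equal(out$report$n_imputed_continuous, 1L)
  expect_true(out$panel$value_imputed[2])

  p2 <- make_panel(c(1, 2, 3), strata = c("a", "a", NA))
  out2 <- impute_missing(p2)
  expect_equal(out2$panel$stratum, c("a", "a", "a"))
  expect_equal(out2$report$n_imputed_categorical, 1L)

  clean <- make_panel(c(4, 5, 6))
  out3 <- impute_missing(clean)
  expect_equal(out3$panel$value, clean$value)
  expect_equal(out3$report$n_imputed_continuous, 0L)

  allna <- make_panel(c(NA_real_, NA_real_))
  expect_error(impute_missing(allna), "unrecoverable")
})

test_that("IQR outlier replacement uses fences and the clean-cell mean", {
  p <- make_panel(c(1, 2, 3, 4, 100))
  out <- replace_outliers_iqr(p, columns = "value")
  expect_equal(out$panel$value, c(1, 2, 3, 4, 2.5))
  expect_equal(out$report$n_outliers_replaced, 1L)
  # fences from type-7 quantiles: Q1 = 2, Q3 = 4, IQR = 2
  expect_equal(unname(out$report$iqr_bounds$value),
               c(2 - 3, 4 + 3))

  const <- make_panel(rep(5, 6))
  expect_equal(replace_outliers_iqr(const,
                                    columns = "value")$panel$value,
               rep(5, 6))

  inside <- make_panel(c(10, 11, 12, 13, 14))
  out2 <- replace_outliers_iqr(inside, columns = "value")
  expect_equal(out2$panel$value, c(10, 11, 12, 13, 14))
  expect_equal(out2$report$n_outliers_replaced, 0L)
})

test_that("outlier replacement is idempotent on its own output", {
  p <- make_panel(c(1, 2, 3, 4, 100, 2, 3, 150))
  once <- replace_outliers_iqr(p, columns = "value")
  twice <- replace_outliers_iqr(once$panel, columns = "value")
  expect_equal(twice$panel$value, once$panel$value)
  expect_equal(twice$report$n_outliers_replaced, 0L)
})

test_that("z-score normalization is exact, invertible, and guarded", {
  p <- make_panel(c(1, 2, 3), sizes = c(10L, 20L, 30L))
  z <- zscore_normalize(p, columns = "value")
  expect_equal(z$value, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  sc <- attr(z, "scaler")
  expect_equal(inverse_zscore(z$value, sc, "value"), c(1, 2, 3),
               tolerance = 1e-10)
  expect_equal(mean(z$value), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z$value - mean(z$value))^2)), 1, tolerance = 1e-9)

  # scaling an already-standardized column is a no-op up to tolerance
  z2 <- zscore_normalize(z, columns = "value")
  expect_equal(z2$value, z$value, tolerance = 1e-10)

  const <- make_panel(rep(2, 4))
  expect_error(zscore_normalize(const, columns = "value"), "value")
})

test_that("the cleaning chain composes: impute, fence, scale", {
  cfg <- synthetic_config(n_states = 1, years = c(1990, 2019), n_strata = 2,
                          missing_rate = 0.15, outlier_rate = 0.1,
                          outlier_magnitude = 10, seed = 12)
  raw <- degrade_panel(generate_state_panel(cfg, 1), cfg)
  step1 <- impute_missing(raw)
  expect_false(any(is.na(step1$panel$value)))        # ready for fences
  step2 <- replace_outliers_iqr(step1$panel)
  expect_false(any(is.na(step2$panel$value)))        # ready for scaling
  z <- zscore_normalize(step2$panel)
  expect_equal(mean(z$value), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z$value - mean(z$value))^2)), 1, tolerance = 1e-9)

  both <- preprocess_panel(raw)
  expect_equal(both$report$n_imputed_continuous,
               step1$report$n_imputed_continuous)
  expect_equal(both$report$n_outliers_replaced,
               step2$report$n_outliers_replaced)
})
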