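# Cleaning chain for surveillance panels: mean/mode imputation, IQR outlier
# replacement, and z-score standardization. The chain is ordered
# impute -> outlier-replace -> scale; each step's output satisfies the next
# step's precondition, and every step reports what it changed so a cleaned
# dataset remains auditable.

#' Read a DNPAO-layout CSV into a state panel
#'
#' Expects at least the columns `YearStart`, `LocationAbbr`, `Data_Value`,
#' `Sample_Size`, `Stratification1`. `YearStart` becomes the time index and
#' `Data_Value` the prevalence target; empty `Data_Value` cells are parsed
#' as missing. Rows are sorted by (stratum, year).
#'
#' @param path Path to a CSV in the CDC "Data, Trends, and Maps" layout.
#' @return A `state_panel` data frame.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  required <- c("YearStart", "LocationAbbr", "Data_Value", "Sample_Size",
                "Stratification1")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0L) {
    stop(sprintf("format error: missing required column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  raw <- trimws(df$Data_Value)
  empty <- is.na(raw) | raw == ""
  value <- suppressWarnings(as.numeric(raw))
  bad <- !empty & is.na(value)
  if (any(bad)) {
    stop(sprintf("parse error: non-numeric Data_Value at line %d: '%s'",
                 which(bad)[1] + 1L, raw[which(bad)[1]]), call. = FALSE)
  }
  value[empty] <- NA_real_
  panel <- data.frame(
    year = as.integer(df$YearStart),
    stratum = df$Stratification1,
    value = value,
    sample_size = suppressWarnings(as.integer(as.numeric(df$Sample_Size))),
    value_missing = empty,
    stringsAsFactors = FALSE
  )
  new_state_panel(panel, df$LocationAbbr[1])
}

new_preprocess_report <- function(n_imputed_continuous = 0L,
                                  n_imputed_categorical = 0L,
                                  n_outliers_replaced = 0L,
                                  iqr_bounds = list()) {
  structure(list(
    n_imputed_continuous = n_imputed_continuous,
    n_imputed_categorical = n_imputed_categorical,
    n_outliers_replaced = n_outliers_replaced,
    iqr_bounds = iqr_bounds,
    quantile_convention = "type 7 (linear interpolation)",
    fence_multiplier = 1.5
  ), class = "preprocess_report")
}

#' Mean/mode imputation of missing panel cells
#'
#' Continuous columns (`value`, `sample_size`) receive the column mean of
#' the observed cells; the categorical `stratum` column receives its most
#' frequent level. Statistics are computed over `fit_idx` rows only (all
#' rows by default), so training-portion statistics can be applied to
#' later years without leakage.
#'
#' @param panel A `state_panel`.
#' @param fit_idx Row indices used to compute imputation statistics.
#' @return A list with elements `panel` (complete; a `value_imputed`
#'   column flags the filled cells so downstream evaluation can avoid
#'   scoring predictions against imputed targets) and `report`
#'   (a `preprocess_report` with imputation counts).
#' @export
impute_missing <- function(panel, fit_idx = seq_len(nrow(panel))) {
  stopifnot(inherits(panel, "state_panel"))
  out <- panel
  out$value_imputed <- is.na(out$value)
  n_cont <- 0L
  for (col in c("value", "sample_size")) {
    miss <- is.na(out[[col]])
    if (all(miss[fit_idx])) {
      stop(sprintf("unrecoverable column: `%s` has no observed values", col),
           call. = FALSE)
    }
    if (any(miss)) {
      out[[col]][miss] <- mean(out[[col]][fit_idx], na.rm = TRUE)
      n_cont <- n_cont + sum(miss)
    }
  }
  n_cat <- 0L
  miss_s <- is.na(out$stratum) | out$stratum == ""
  if (any(miss_s)) {
    observed <- out$stratum[fit_idx][!(is.na(out$stratum[fit_idx]) |
                                         out$stratum[fit_idx] == "")]
    if (length(observed) == 0L) {
      stop("unrecoverable column: `stratum` has no observed values",
           call. = FALSE)
    }
    tab <- sort(table(observed), decreasing = TRUE)
    out$stratum[miss_s] <- names(tab)[1]
    n_cat <- sum(miss_s)
  }
  out$value_missing <- FALSE
  list(panel = new_state_panel(out, attr(panel, "state_code")),
       report = new_preprocess_report(n_imputed_continuous = n_cont,
                                      n_imputed_categorical = n_cat))
}

#' Replace IQR outliers by the clean-cell column mean
#'
#' Per column, the first and third quartiles are computed with linear
#' interpolation between order statistics; cells outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are replaced by the mean of the cells
#' inside the fences, so the replacement value is not contaminated by the
#' outliers themselves. A zero-IQR (constant) column is left untouched.
#'
#' @param panel A complete `state_panel` (run after [impute_missing()]).
#' @param columns Numeric columns to screen.
#' @param fit_idx Row indices used to compute quartiles and the
#'   replacement mean.
#' @return A list with `panel` and `report` (replacement count and the
#'   per-column fence bounds in original units).
#' @export
replace_outliers_iqr <- function(panel, columns = c("value", "sample_size"),
                                 fit_idx = seq_len(nrow(panel))) {
  stopifnot(inherits(panel, "state_panel"))
  if (any(is.na(panel$value))) {
    stop("replace_outliers_iqr() expects an imputed panel with no missing values",
         call. = FALSE)
  }
  out <- panel
  n_rep <- 0L
  bounds <- list()
  for (col in columns) {
    x_fit <- out[[col]][fit_idx]
    q <- stats::quantile(x_fit, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    bounds[[col]] <- c(lower = lo, upper = hi)
    if (iqr == 0) next
    flag <- out[[col]] < lo | out[[col]] > hi
    if (any(flag)) {
      keep_fit <- x_fit >= lo & x_fit <= hi
      out[[col]][flag] <- mean(x_fit[keep_fit])
      n_rep <- n_rep + sum(flag)
    }
  }
  list(panel = new_state_panel(out, attr(panel, "state_code")),
       report = new_preprocess_report(n_outliers_replaced = n_rep,
                                      iqr_bounds = bounds))
}

#' Z-score standardization with a recorded scaler
#'
#' Centers and scales each requested column to mean 0, sd 1 using the
#' population standard deviation (divide by N). The `(mean, sd)` pairs are
#' recorded so predictions can be mapped back to original percent units
#' with [inverse_zscore()]. Statistics come from `fit_idx` rows only, so a
#' training-period scaler can be applied to later years.
#'
#' @param x A `state_panel` or a `feature_matrix`.
#' @param ... Passed to methods.
#' @return The same type of object with scaled columns and a `scaler`
#'   attribute (list of `c(mean, sd)` per column).
#' @export
zscore_normalize <- function(x, ...) UseMethod("zscore_normalize")

stf_fit_scaler <- function(values, name) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s <= 0) {
    stop(sprintf("degenerate scale: column `%s` is constant", name),
         call. = FALSE)
  }
  c(mean = m, sd = s)
}

#' @rdname zscore_normalize
#' @param columns Columns to scale.
#' @param fit_idx Row indices used to compute the scaling statistics.
#' @export
zscore_normalize.state_panel <- function(x, columns = c("value", "sample_size"),
                                         fit_idx = seq_len(nrow(x)), ...) {
  if (any(is.na(x$value))) {
    stop("zscore_normalize() expects a panel with no missing values",
         call. = FALSE)
  }
  scaler <- list()
  for (col in columns) {
    sc <- stf_fit_scaler(x[[col]][fit_idx], col)
    x[[col]] <- (x[[col]] - sc["mean"]) / sc["sd"]
    scaler[[col]] <- sc
  }
  out <- new_state_panel(x, attr(x, "state_code"))
  attr(out, "scaler") <- scaler
  out
}

#' @rdname zscore_normalize
#' @export
zscore_normalize.feature_matrix <- function(x, columns = NULL,
                                            fit_idx = NULL, ...) {
  if (is.null(fit_idx)) fit_idx <- which(x$valid_mask)
  if (is.null(columns)) {
    onehot <- grepl("^strat_", x$feature_names)
    columns <- x$feature_names[!onehot]
  }
  scaler <- list()
  for (col in columns) {
    j <- match(col, x$feature_names)
    sc <- stf_fit_scaler(x$X[fit_idx, j], col)
    x$X[, j] <- (x$X[, j] - sc["mean"]) / sc["sd"]
    scaler[[col]] <- sc
  }
  sc_y <- stf_fit_scaler(x$y[fit_idx], "y")
  x$y <- (x$y - sc_y["mean"]) / sc_y["sd"]
  scaler[["y"]] <- sc_y
  x$scaler <- scaler
  x
}

#' Invert a recorded z-score transform
#'
#' @param values Scaled numeric values.
#' @param scaler The scaler attribute recorded by [zscore_normalize()].
#' @param column Which column's `(mean, sd)` pair to invert with.
#' @return Values on the original scale.
#' @export
inverse_zscore <- function(values, scaler, column = "y") {
  sc <- scaler[[column]]
  if (is.null(sc)) stop(sprintf("no scaler recorded for `%s`", column),
                        call. = FALSE)
  values * sc["sd"] + sc["mean"]
}

#' Run the full cleaning chain on one panel
#'
#' Applies [impute_missing()] then [replace_outliers_iqr()] and merges the
#' two step reports. Scaling is deliberately left to the feature level
#' (see [zscore_normalize()]), where train-only statistics are applied.
#'
#' @param panel A `state_panel`.
#' @param fit_idx Row indices used for imputation statistics.
#' @param outlier_fit_idx Row indices used for the IQR fences. Defaults to
#'   `fit_idx`; pass all rows to screen outliers over the whole series,
#'   which is the sensible choice for a strongly trending series where
#'   training-period fences would flag every later observation.
#' @return A list with `panel` (clean, original units) and `report`.
#' @export
preprocess_panel <- function(panel, fit_idx = seq_len(nrow(panel)),
                             outlier_fit_idx = fit_idx) {
  imp <- impute_missing(panel, fit_idx = fit_idx)
  out <- replace_outliers_iqr(imp$panel, fit_idx = outlier_fit_idx)
  report <- new_preprocess_report(
    n_imputed_continuous = imp$report$n_imputed_continuous,
    n_imputed_categorical = imp$report$n_imputed_categorical,
    n_outliers_replaced = out$report$n_outliers_replaced,
    iqr_bounds = out$report$iqr_bounds
  )
  list(panel = out$panel, report = report)
}
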