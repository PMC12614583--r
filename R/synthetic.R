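# Synthetic BRFSS-like state panels.
#
# Each state carries one yearly obesity-prevalence series per stratification
# category. The generative law is a linear secular trend plus a stationary
# AR(1) disturbance around it, with a constant per-stratum level shift:
#
#   value[t] = base_level + trend_per_year * (year[t] - year[1])
#              + offset[stratum] + e[t],    e[t] = ar * e[t-1] + N(0, noise_sd)
#
# Degradation then masks cells completely at random and injects occasional
# level-shift outliers, so the preprocessing chain has something real to do.

stf_local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

stf_check_range <- function(value, field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(value) || length(value) != 1L || is.na(value) ||
    value < lo || value > hi ||
    (lo_open && value == lo) || (hi_open && value == hi)
  if (bad) {
    stop(sprintf("invalid configuration: `%s` must be in %s%s, %s%s",
                 field, if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(value)
}

#' Configuration for the synthetic panel generator
#'
#' Defines the study conditions under which panels are simulated: number of
#' states, year range, stratification categories, and the parameters of the
#' trend + AR(1) generative law, plus the degradation rates applied
#' afterwards (missingness is completely at random; outliers are level
#' shifts measured in multiples of the innovation standard deviation).
#'
#' @param n_states Number of states to simulate.
#' @param years Inclusive integer year range, length-2 vector.
#' @param n_strata Number of stratification categories per state.
#' @param base_level Baseline prevalence in percent at the first year.
#' @param trend_per_year Linear trend in percentage points per year.
#' @param ar_coefficient AR(1) coefficient of the disturbance, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation in percentage points.
#' @param missing_rate Probability a cell is masked, in `[0, 0.5]`.
#' @param outlier_rate Probability a non-masked cell is shifted, in `[0, 0.5]`.
#' @param outlier_magnitude Shift size in multiples of `noise_sd`.
#' @param seed Integer seed; all panel randomness derives from it.
#' @return A `synthetic_config` list with validated fields.
#' @examples
#' cfg <- synthetic_config(n_states = 2, years = c(2000, 2010))
#' panel <- generate_state_panel(cfg, 1)
#' head(panel)
#' @export
synthetic_config <- function(n_states = 10L,
                             years = c(1984L, 2023L),
                             n_strata = 2L,
                             base_level = 30,
                             trend_per_year = 0.5,
                             ar_coefficient = 0.6,
                             noise_sd = 0.5,
                             missing_rate = 0.1,
                             outlier_rate = 0.02,
                             outlier_magnitude = 6,
                             seed = 1L) {
  if (length(years) != 2L || years[2] < years[1]) {
    stop("invalid configuration: `years` must be an inclusive range c(first, last)",
         call. = FALSE)
  }
  stf_check_range(n_states, "n_states", 1, 1e4)
  stf_check_range(n_strata, "n_strata", 1, 100)
  stf_check_range(base_level, "base_level", 0, 100)
  stf_check_range(ar_coefficient, "ar_coefficient", 0, 1, hi_open = TRUE)
  stf_check_range(noise_sd, "noise_sd", 0, Inf)
  stf_check_range(missing_rate, "missing_rate", 0, 0.5)
  stf_check_range(outlier_rate, "outlier_rate", 0, 0.5)
  stf_check_range(outlier_magnitude, "outlier_magnitude", 0, Inf)
  stf_check_range(seed, "seed", -2^31 + 1, 2^31 - 1)
  structure(list(
    n_states = as.integer(n_states), years = as.integer(years),
    n_strata = as.integer(n_strata), base_level = base_level,
    trend_per_year = trend_per_year, ar_coefficient = ar_coefficient,
    noise_sd = noise_sd, missing_rate = missing_rate,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

stf_state_code <- function(state_index) {
  if (state_index <= length(datasets::state.abb)) datasets::state.abb[state_index]
  else sprintf("S%02d", state_index)
}

stf_state_name <- function(state_index) {
  if (state_index <= length(datasets::state.name)) datasets::state.name[state_index]
  else sprintf("State %02d", state_index)
}

stf_stratum_labels <- function(n_strata) {
  base <- c("Male", "Female", "18 - 24", "25 - 34", "35 - 44", "45 - 54",
            "55 - 64", "65 or older")
  if (n_strata <= length(base)) base[seq_len(n_strata)]
  else c(base, sprintf("Group %d", seq_len(n_strata - length(base))))
}

new_state_panel <- function(df, state_code) {
  df <- df[order(df$stratum, df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, state_code = state_code, class = c("state_panel", "data.frame"))
}

#' Simulate one state's complete panel
#'
#' Produces one row per (year, stratum) cell with no missing values;
#' deterministic given `(config$seed, state_index)`. Stratum level offsets
#' are drawn once per panel from N(0, 2) percentage points, mimicking the
#' level differences between gender / age-group strata in surveillance
#' exports.
#'
#' @param config A [synthetic_config()].
#' @param state_index 1-based state number, at most `config$n_states`.
#' @return A `state_panel` data frame with columns `year`, `stratum`,
#'   `value` (percent), `sample_size`, `value_missing`.
#' @export
generate_state_panel <- function(config, state_index) {
  stopifnot(inherits(config, "synthetic_config"))
  if (state_index < 1 || state_index > config$n_states) {
    stop("`state_index` must be between 1 and config$n_states", call. = FALSE)
  }
  guard <- stf_local_seed(config$seed + 7919L * as.integer(state_index))
  on.exit(guard$restore())

  years <- seq(config$years[1], config$years[2])
  strata <- stf_stratum_labels(config$n_strata)
  # a single stratum has no level shift, so a noiseless panel follows the
  # closed-form trend exactly
  offsets <- if (config$n_strata == 1L) 0 else stats::rnorm(config$n_strata, 0, 2)
  rows <- vector("list", config$n_strata)
  for (s in seq_along(strata)) {
    e <- 0
    vals <- numeric(length(years))
    for (t in seq_along(years)) {
      e <- config$ar_coefficient * e + stats::rnorm(1, 0, config$noise_sd)
      vals[t] <- config$base_level +
        config$trend_per_year * (years[t] - years[1]) + offsets[s] + e
    }
    vals <- pmin(pmax(vals, 0), 100)
    rows[[s]] <- data.frame(
      year = years, stratum = strata[s], value = vals,
      sample_size = pmax(50L, as.integer(round(stats::rlnorm(length(years),
                                                             log(1200), 0.4)))),
      value_missing = FALSE, stringsAsFactors = FALSE
    )
  }
  new_state_panel(do.call(rbind, rows), stf_state_code(state_index))
}

#' Mask and contaminate a complete panel
#'
#' Applies the degradation pattern the preprocessing chain is designed to
#' repair: each value is masked completely at random with probability
#' `missing_rate`; independently, each surviving value is shifted by
#' `+/- outlier_magnitude * noise_sd` with probability `outlier_rate`.
#' The input panel is not modified.
#'
#' @param panel A complete `state_panel` (no missing values).
#' @param config A [synthetic_config()] supplying the rates and seed.
#' @param salt Integer mixed into the seed so different panels degrade
#'   independently under one config.
#' @return A new `state_panel`; masked cells have `value = NA` and
#'   `value_missing = TRUE`.
#' @export
degrade_panel <- function(panel, config, salt = 0L) {
  stopifnot(inherits(panel, "state_panel"), inherits(config, "synthetic_config"))
  if (any(panel$value_missing)) {
    stop("degrade_panel() expects a complete panel", call. = FALSE)
  }
  guard <- stf_local_seed(config$seed + 104729L + 13L * as.integer(salt))
  on.exit(guard$restore())

  out <- panel
  n <- nrow(out)
  mask <- stats::runif(n) < config$missing_rate
  shift <- stats::runif(n) < config$outlier_rate & !mask
  sign <- sample(c(-1, 1), n, replace = TRUE)
  out$value[shift] <- pmin(pmax(
    out$value[shift] + sign[shift] * config$outlier_magnitude * config$noise_sd,
    0), 100)
  out$value[mask] <- NA_real_
  out$value_missing <- mask
  new_state_panel(out, attr(panel, "state_code"))
}

#' Simulate all states under one configuration
#'
#' @param config A [synthetic_config()].
#' @param degrade Apply [degrade_panel()] to each state's panel?
#' @return Named list of `state_panel` objects, one per state.
#' @export
generate_panels <- function(config, degrade = TRUE) {
  panels <- lapply(seq_len(config$n_states), function(i) {
    p <- generate_state_panel(config, i)
    if (degrade) p <- degrade_panel(p, config, salt = i)
    p
  })
  names(panels) <- vapply(panels, function(p) attr(p, "state_code"), character(1))
  panels
}

#' Write a panel as a DNPAO "Data, Trends, and Maps" style CSV
#'
#' Emits the column layout of the CDC export (YearStart/YearEnd,
#' LocationAbbr/LocationDesc, Class/Topic/Question, Data_Value,
#' Data_Value_Unit, Data_Value_Type, Sample_Size, GeoLocation,
#' Stratification1) so real extracts are drop-in compatible with
#' [read_panel_csv()]. Masked cells become empty `Data_Value` fields.
#'
#' @param panel A `state_panel`.
#' @param path Output CSV path.
#' @param location_desc Human-readable state name; defaults to a lookup on
#'   the panel's state code.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, location_desc = NULL) {
  stopifnot(inherits(panel, "state_panel"))
  code <- attr(panel, "state_code")
  if (is.null(location_desc)) {
    hit <- match(code, datasets::state.abb)
    location_desc <- if (!is.na(hit)) datasets::state.name[hit] else code
  }
  df <- data.frame(
    YearStart = panel$year,
    YearEnd = panel$year,
    LocationAbbr = code,
    LocationDesc = location_desc,
    Class = "Obesity / Weight Status",
    Topic = "Obesity / Weight Status",
    Question = "Percent of adults aged 18 years and older who have obesity",
    Data_Value = ifelse(panel$value_missing, "", format(panel$value, digits = 10)),
    Data_Value_Unit = "%",
    Data_Value_Type = "Crude Prevalence",
    Sample_Size = panel$sample_size,
    GeoLocation = "",
    Stratification1 = panel$stratum,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
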