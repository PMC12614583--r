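# Engineered features for next-step prevalence forecasting: lagged values,
# first/second differences, trailing rolling means, survey covariates, and
# one-hot stratification indicators. All features at time t use information
# up to and including t only; warm-up rows where any feature is undefined
# are masked, never zero-filled.

#' Feature-set specification
#'
#' @param lags Lag orders of the target, in years.
#' @param diff_orders Difference orders, subset of `c(1, 2)`.
#' @param roll_windows Trailing rolling-mean window lengths, in years.
#' @param include_sample_size Include the survey sample size as a feature?
#' @param include_year Include the calendar year as a feature?
#' @param one_hot_strata Append one-hot stratification indicators?
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(lags = c(1L, 2L),
                         diff_orders = c(1L, 2L),
                         roll_windows = c(3L, 5L),
                         include_sample_size = TRUE,
                         include_year = TRUE,
                         one_hot_strata = TRUE) {
  if (length(lags) && any(lags < 1)) stop("all lags must be >= 1", call. = FALSE)
  if (length(roll_windows) && any(roll_windows < 1)) {
    stop("all roll windows must be >= 1", call. = FALSE)
  }
  if (length(diff_orders) && !all(diff_orders %in% c(1L, 2L))) {
    stop("diff orders must be in {1, 2}", call. = FALSE)
  }
  structure(list(
    lags = sort(unique(as.integer(lags))),
    diff_orders = sort(unique(as.integer(diff_orders))),
    roll_windows = sort(unique(as.integer(roll_windows))),
    include_sample_size = isTRUE(include_sample_size),
    include_year = isTRUE(include_year),
    one_hot_strata = isTRUE(one_hot_strata)
  ), class = "feature_spec")
}

#' One-hot encode a categorical vector
#'
#' Columns are ordered by first appearance of each level; every row has
#' exactly one 1.
#'
#' @param labels Character (or factor) vector, length >= 1.
#' @return A list with `matrix` (n x n_levels, 0/1) and `levels`.
#' @export
one_hot_encode <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("at least one label required", call. = FALSE)
  levels <- unique(labels)
  m <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  list(matrix = m, levels = levels)
}

stf_warmup <- function(spec) {
  max(c(0L, spec$lags, spec$roll_windows - 1L, spec$diff_orders))
}

stf_series_features <- function(y, spec) {
  n <- length(y)
  cols <- list()
  for (k in spec$lags) {
    cols[[paste0("lag", k)]] <- c(rep(NA_real_, k), y[seq_len(n - k)])
  }
  if (length(spec$diff_orders)) {
    d1 <- c(NA_real_, diff(y))
    if (1L %in% spec$diff_orders) cols[["diff1"]] <- d1
    if (2L %in% spec$diff_orders) cols[["diff2"]] <- c(NA_real_, diff(d1))
  }
  for (w in spec$roll_windows) {
    rw <- rep(NA_real_, n)
    if (n >= w) {
      cs <- cumsum(y)
      rw[w:n] <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
    }
    cols[[paste0("roll", w)]] <- rw
  }
  cols
}

#' Build the engineered feature matrix for one clean panel
#'
#' Within each stratum's yearly series, computes `lag_k[t] = y[t-k]`,
#' `diff1[t] = y[t] - y[t-1]`, `diff2[t] = diff1[t] - diff1[t-1]`, and
#' trailing means `roll_w[t] = mean(y[t-w+1 .. t])`, then appends the
#' optional survey covariates and one-hot stratum indicators. The first
#' `max(lags, roll_windows - 1, diff_orders)` rows of each stratum are
#' masked as warm-up.
#'
#' @param panel A complete `state_panel` sorted by (stratum, year).
#' @param spec A [feature_spec()].
#' @return A `feature_matrix` list: `times`, `strata`, `X`,
#'   `feature_names`, `y`, `valid_mask`.
#' @export
build_features <- function(panel, spec = feature_spec()) {
  stopifnot(inherits(panel, "state_panel"), inherits(spec, "feature_spec"))
  if (any(is.na(panel$value))) {
    stop("build_features() expects a panel with no missing values", call. = FALSE)
  }
  warmup <- stf_warmup(spec)
  strata <- unique(panel$stratum)
  oh <- if (spec$one_hot_strata) one_hot_encode(panel$stratum) else NULL

  blocks <- list(); masks <- list()
  for (s in strata) {
    rows <- which(panel$stratum == s)
    ys <- panel$value[rows]
    if (length(ys) < warmup + 1L) {
      stop(sprintf(
        "insufficient history: stratum '%s' has %d rows but warm-up needs %d",
        s, length(ys), warmup + 1L), call. = FALSE)
    }
    cols <- stf_series_features(ys, spec)
    if (spec$include_sample_size) cols[["sample_size"]] <- panel$sample_size[rows]
    if (spec$include_year) cols[["year"]] <- panel$year[rows]
    blocks[[s]] <- do.call(cbind, cols)
    m <- rep(TRUE, length(ys))
    if (warmup > 0L) m[seq_len(warmup)] <- FALSE
    masks[[s]] <- m
  }
  X <- do.call(rbind, blocks)
  if (!is.null(oh)) {
    colnames(oh$matrix) <- paste0("strat_", oh$levels)
    X <- cbind(X, oh$matrix)
  }
  valid <- unlist(masks, use.names = FALSE)
  structure(list(
    times = panel$year,
    strata = panel$stratum,
    X = X,
    feature_names = colnames(X),
    y = panel$value,
    y_imputed = if (is.null(panel$value_imputed)) rep(FALSE, nrow(panel))
                else panel$value_imputed,
    valid_mask = valid,
    state_code = attr(panel, "state_code"),
    spec = spec
  ), class = "feature_matrix")
}

#' Assemble sliding-window supervised samples
#'
#' Slides a length-`window` window over the valid rows of each stratum and
#' pairs it with the target at the step immediately after the window. No
#' window crosses a stratum boundary and no shuffling across time occurs
#' here; chronological splitting is applied downstream.
#'
#' @param fm A `feature_matrix`.
#' @param window Input window length in time steps (>= 1).
#' @return A `supervised_set`: list of samples, each with `X`
#'   (window x F), `y_hist` (the window's own target values, used by the
#'   scalar-input baseline), `y` (next-step target), `time` (target year),
#'   `stratum`, and `state`; attributes `feature_names` and `window`.
#' @export
assemble_supervised <- function(fm, window = 5L) {
  stopifnot(inherits(fm, "feature_matrix"), window >= 1L)
  samples <- list()
  for (s in unique(fm$strata)) {
    rows <- which(fm$strata == s & fm$valid_mask)
    if (length(rows) < window + 1L) {
      stop(sprintf(
        "insufficient history: stratum '%s' has %d valid rows; window %d needs %d",
        s, length(rows), window, window + 1L), call. = FALSE)
    }
    for (i in seq_len(length(rows) - window)) {
      idx <- rows[i:(i + window - 1L)]
      nxt <- rows[i + window]
      samples[[length(samples) + 1L]] <- list(
        X = fm$X[idx, , drop = FALSE],
        y_hist = fm$y[idx],
        y = fm$y[nxt],
        y_imputed = fm$y_imputed[nxt],
        time = fm$times[nxt],
        stratum = s,
        state = fm$state_code
      )
    }
  }
  structure(samples, feature_names = fm$feature_names, window = window,
            class = "supervised_set")
}

#' Chronological train/validation/test split
#'
#' Within each (state, stratum) series, the earliest `fracs[1]` of samples
#' (by target year) form the training set, the next `fracs[2]` the
#' validation set, and the remainder the test set. No sample is ever
#' shuffled across time.
#'
#' @param samples A `supervised_set` (or plain list of samples).
#' @param fracs Length-3 non-negative fractions summing to 1.
#' @return List with `train`, `validation`, `test` sample lists.
#' @export
split_supervised <- function(samples, fracs = c(0.7, 0.15, 0.15)) {
  stopifnot(length(fracs) == 3L, abs(sum(fracs) - 1) < 1e-8, all(fracs >= 0))
  keys <- vapply(samples, function(s) paste(s$state, s$stratum, sep = "\r"),
                 character(1))
  train <- list(); val <- list(); test <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    idx <- idx[order(vapply(samples[idx], function(s) s$time, numeric(1)))]
    n <- length(idx)
    n_tr <- max(1L, floor(fracs[1] * n))
    n_va <- floor(fracs[2] * n)
    train <- c(train, samples[idx[seq_len(n_tr)]])
    if (n_va > 0L) val <- c(val, samples[idx[n_tr + seq_len(n_va)]])
    if (n > n_tr + n_va) test <- c(test, samples[idx[(n_tr + n_va + 1L):n]])
  }
  fn <- attr(samples, "feature_names"); w <- attr(samples, "window")
  wrap <- function(x) structure(x, feature_names = fn, window = w,
                                class = "supervised_set")
  list(train = wrap(train), validation = wrap(val), test = wrap(test))
}
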