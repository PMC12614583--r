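# The five-metric forecast evaluation protocol: MAE, RMSE, sMAPE (in
# percent, bounded by 200), R-squared, and MASE (error relative to the
# naive one-step forecast of the evaluation series itself), plus
# paired t-tests across matched per-state results and mean +/- sd
# aggregation over random seeds.

#' Compute the five forecast metrics
#'
#' * `MAE = mean(|y - yhat|)`
#' * `RMSE = sqrt(mean((y - yhat)^2))`
#' * `sMAPE = 100/N * sum(|y - yhat| / ((|y| + |yhat|) / 2))`, a term with
#'   `|y| + |yhat| = 0` contributing 0
#' * `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`
#' * `MASE = mean(|y - yhat|) / mean(|y[i] - y[i-1]|)` with the naive
#'   denominator taken over the evaluation series `y` itself
#'   (`mase_denominator = "evaluation"`), or over a supplied training
#'   series (`"insample"`, the textbook variant).
#'
#' Metrics are intended to be computed on the original percent scale.
#'
#' @param y True values (length >= 2 for MASE).
#' @param y_hat Predictions, same length.
#' @param mase_denominator `"evaluation"` or `"insample"`.
#' @param insample Training-period series for the `"insample"` variant.
#' @return A `metrics_report` list with `mae`, `rmse`, `smape`, `r2`,
#'   `mase`, and `n`.
#' @export
compute_metrics <- function(y, y_hat,
                            mase_denominator = c("evaluation", "insample"),
                            insample = NULL) {
  mase_denominator <- match.arg(mase_denominator)
  if (length(y) != length(y_hat)) {
    stop("shape error: y and y_hat must have equal length", call. = FALSE)
  }
  n <- length(y)
  err <- y - y_hat
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  denom <- (abs(y) + abs(y_hat)) / 2
  terms <- ifelse(denom == 0, 0, abs(err) / denom)
  smape <- 100 * mean(terms)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: `y` is constant (zero variance)",
         call. = FALSE)
  }
  r2 <- 1 - sum(err^2) / ss_tot
  naive_base <- if (mase_denominator == "insample") {
    if (is.null(insample) || length(insample) < 2L) {
      stop("`insample` series of length >= 2 required for the in-sample MASE",
           call. = FALSE)
    }
    insample
  } else {
    if (n < 2L) stop("MASE needs at least 2 evaluation points", call. = FALSE)
    y
  }
  naive <- mean(abs(diff(naive_base)))
  if (naive == 0) {
    stop("MASE undefined: the naive one-step error of the series is zero",
         call. = FALSE)
  }
  mase <- mae / naive
  structure(list(mae = mae, rmse = rmse, smape = smape, r2 = r2,
                 mase = mase, n = n), class = "metrics_report")
}

#' Paired two-sided t-test between matched per-state results
#'
#' Classical paired t-test on the per-state differences with
#' `df = n_pairs - 1`. A zero-variance difference vector (identical
#' results, or a constant offset) has no defined t statistic and raises a
#' degenerate-test error.
#'
#' @param method_a,method_b Equal-length (>= 2) metric vectors over the
#'   same states.
#' @return A `significance_report` list with `t`, `p_value`, `df`,
#'   `mean_difference`, `n_pairs`.
#' @export
paired_ttest <- function(method_a, method_b) {
  n <- length(method_a)
  if (length(method_b) != n || n < 2L) {
    stop("paired test needs two equal-length vectors with >= 2 pairs",
         call. = FALSE)
  }
  d <- method_a - method_b
  if (stats::sd(d) == 0) {
    stop("degenerate test: per-state differences have zero variance",
         call. = FALSE)
  }
  ht <- stats::t.test(method_a, method_b, paired = TRUE,
                      alternative = "two.sided")
  structure(list(t = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter), mean_difference = mean(d),
                 n_pairs = n), class = "significance_report")
}

#' Aggregate metric reports over random seeds
#'
#' Per-metric mean and sample standard deviation (n - 1) across seeds;
#' a single report is aggregated with sd 0 and flagged.
#'
#' @param reports List of `metrics_report` objects, one per seed.
#' @return A `metrics_report` carrying the means, plus `per_seed` and
#'   `mean_sd` (matrix with rows mean/sd) and `single_seed` flag.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report", call. = FALSE)
  metrics <- c("mae", "rmse", "smape", "r2", "mase")
  per_seed <- vapply(reports, function(r) unlist(r[metrics]),
                     numeric(length(metrics)))
  per_seed <- matrix(per_seed, nrow = length(metrics),
                     dimnames = list(metrics, NULL))
  mean_v <- rowMeans(per_seed)
  sd_v <- if (ncol(per_seed) > 1L) apply(per_seed, 1L, stats::sd)
          else stats::setNames(rep(0, length(metrics)), metrics)
  out <- as.list(mean_v)
  out$n <- sum(vapply(reports, function(r) r$n, numeric(1)))
  out$per_seed <- per_seed
  out$mean_sd <- rbind(mean = mean_v, sd = sd_v)
  out$single_seed <- ncol(per_seed) == 1L
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "MAE %.4f | RMSE %.4f | sMAPE %.4f%% | R2 %.4f | MASE %.4f (n = %d)\n",
    x$mae, x$rmse, x$smape, x$r2, x$mase, x$n))
  invisible(x)
}
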