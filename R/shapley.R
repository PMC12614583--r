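# Shapley-value attributions for the engineered features. The estimator
# is model-agnostic: absent features are replaced by background draws.
# For F <= 10 an exact mode enumerates all 2^F coalitions, which the
# permutation-sampling estimator (with antithetic permutation pairs) is
# checked against in tests. Attributions are in the units of the model
# output (percent prevalence).

stf_coalition_value <- function(f, x, background, masks) {
  # masks: n_masks x F logical; returns v(S) = mean_bg f(x_S, bg_~S)
  M <- nrow(background); F_n <- length(x)
  n_masks <- nrow(masks)
  rows <- matrix(0, n_masks * M, F_n)
  for (k in seq_len(n_masks)) {
    block <- background
    block[, masks[k, ]] <- matrix(x[masks[k, ]], M, sum(masks[k, ]),
                                  byrow = TRUE)
    rows[(k - 1L) * M + seq_len(M), ] <- block
  }
  preds <- f(rows)
  rowMeans(matrix(preds, n_masks, M, byrow = TRUE))
}

stf_shapley_exact_row <- function(f, x, background) {
  F_n <- length(x)
  n_masks <- 2L^F_n
  masks <- matrix(FALSE, n_masks, F_n)
  for (j in seq_len(F_n)) {
    masks[, j] <- bitwAnd(seq_len(n_masks) - 1L, 2L^(j - 1L)) > 0L
  }
  v <- stf_coalition_value(f, x, background, masks)
  sizes <- rowSums(masks)
  # coalition weight |S|! (F - |S| - 1)! / F!; the full coalition never
  # appears as a "without j" set, so its weight is zeroed
  rest <- pmax(F_n - sizes - 1L, 0L)
  w <- factorial(sizes) * factorial(rest) / factorial(F_n)
  w[sizes >= F_n] <- 0
  phi <- numeric(F_n)
  bit <- 2L^(seq_len(F_n) - 1L)
  code <- seq_len(n_masks) - 1L
  for (j in seq_len(F_n)) {
    without <- which(!masks[, j])
    with_j <- match(code[without] + bit[j], code)
    phi[j] <- sum(w[without] * (v[with_j] - v[without]))
  }
  phi
}

stf_shapley_sample_row <- function(f, x, background, n_permutations) {
  F_n <- length(x)
  M <- nrow(background)
  half <- ceiling(n_permutations / 2)
  phi <- numeric(F_n)
  contrib <- matrix(0, 0L, F_n)
  n_used <- 0L
  for (p in seq_len(half)) {
    perm <- sample.int(F_n)
    for (ord in list(perm, rev(perm))) {
      if (n_used >= n_permutations) break
      bg <- background[(n_used %% M) + 1L, ]
      walk <- matrix(bg, F_n + 1L, F_n, byrow = TRUE)
      cur <- bg
      for (k in seq_len(F_n)) {
        cur[ord[k]] <- x[ord[k]]
        walk[k + 1L, ] <- cur
      }
      preds <- f(walk)
      delta <- diff(preds)
      row_c <- numeric(F_n)
      row_c[ord] <- delta
      contrib <- rbind(contrib, row_c)
      phi <- phi + row_c
      n_used <- n_used + 1L
    }
  }
  list(phi = phi / n_used,
       se = apply(contrib, 2L, stats::sd) / sqrt(n_used))
}

#' Shapley attributions of a predictor over evaluation rows
#'
#' Decomposes each prediction into per-feature contributions that sum,
#' together with the background expectation, to the model output
#' (efficiency). `mode = "exact"` enumerates all `2^F` coalitions
#' (`F <= 10`); `mode = "sampling"` uses permutation sampling with
#' antithetic permutation pairs and cycled background rows, deterministic
#' given `seed`. `mode = "auto"` picks exact when feasible.
#'
#' @param f Predictor: a function mapping an `n x F` matrix to a length-n
#'   numeric vector.
#' @param X `N x F` matrix of rows to explain.
#' @param background `M x F` matrix of reference rows (`M >= 1`).
#' @param n_permutations Permutations per row in sampling mode (>= 1).
#' @param seed Integer seed for sampling mode.
#' @param mode `"auto"`, `"exact"`, or `"sampling"`.
#' @param feature_names Optional column labels.
#' @return An `attribution_report`: `shap_values` (`N x F`),
#'   `base_value`, `importance` (ranked mean absolute attribution),
#'   `method`, and `se` (sampling mode only).
#' @export
shapley_attributions <- function(f, X, background, n_permutations = 200L,
                                 seed = 1L,
                                 mode = c("auto", "exact", "sampling"),
                                 feature_names = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X); background <- as.matrix(background)
  if (nrow(background) < 1L) stop("background must have >= 1 row",
                                  call. = FALSE)
  if (n_permutations < 1L) {
    stop("configuration error: n_permutations must be >= 1", call. = FALSE)
  }
  F_n <- ncol(X)
  if (mode == "auto") mode <- if (F_n <= 10L) "exact" else "sampling"
  if (mode == "exact" && F_n > 10L) {
    stop("exact mode enumerates 2^F coalitions and requires F <= 10",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(F_n))
  }
  shap <- matrix(0, nrow(X), F_n, dimnames = list(NULL, feature_names))
  se <- NULL
  if (mode == "exact") {
    base_value <- mean(f(background))
    for (i in seq_len(nrow(X))) {
      shap[i, ] <- stf_shapley_exact_row(f, X[i, ], background)
    }
  } else {
    # the sampling estimator telescopes f(x) - f(bg_row) per permutation,
    # so efficiency is exact against the mean over the rows actually used
    used <- (seq_len(n_permutations) - 1L) %% nrow(background) + 1L
    base_value <- mean(f(background[used, , drop = FALSE]))
    guard <- stf_local_seed(seed)
    on.exit(guard$restore())
    se <- matrix(0, nrow(X), F_n, dimnames = list(NULL, feature_names))
    for (i in seq_len(nrow(X))) {
      r <- stf_shapley_sample_row(f, X[i, ], background, n_permutations)
      shap[i, ] <- r$phi
      se[i, ] <- r$se
    }
  }
  report <- structure(list(
    shap_values = shap, base_value = base_value,
    feature_names = feature_names, method = mode,
    n_permutations = if (mode == "sampling") as.integer(n_permutations)
                     else NA_integer_,
    se = se
  ), class = "attribution_report")
  report$importance <- importance_summary(report)
  report
}

#' Rank features by mean absolute attribution
#'
#' Ties are broken alphabetically by feature name.
#'
#' @param report An `attribution_report`.
#' @return Data frame with `feature` and `mean_abs_shap`, sorted
#'   descending.
#' @export
importance_summary <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  score <- colMeans(abs(report$shap_values))
  ord <- order(-score, report$feature_names)
  data.frame(feature = report$feature_names[ord],
             mean_abs_shap = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Dependence triples for attribution plots
#'
#' For each feature, pairs its values with its attributions and with the
#' values of the interacting feature — the one whose values correlate
#' most strongly (in absolute Pearson correlation) with the feature's
#' attributions, mirroring standard dependence-plot coloring.
#'
#' @param report An `attribution_report`.
#' @param X The `N x F` matrix the report was computed on.
#' @param features Features to tabulate (default: all).
#' @return Data frame with `feature`, `value`, `shap`,
#'   `interacting_feature`, `interacting_value`.
#' @export
shap_dependence <- function(report, X, features = NULL) {
  stopifnot(inherits(report, "attribution_report"))
  X <- as.matrix(X)
  fn <- report$feature_names
  if (is.null(features)) features <- fn
  out <- list()
  for (f in features) {
    j <- match(f, fn)
    others <- setdiff(seq_along(fn), j)
    inter <- NA_character_
    if (length(others) > 0L && stats::sd(report$shap_values[, j]) > 0) {
      cors <- vapply(others, function(k) {
        if (stats::sd(X[, k]) == 0) return(0)
        abs(stats::cor(X[, k], report$shap_values[, j]))
      }, numeric(1))
      inter <- fn[others[which.max(cors)]]
    }
    out[[f]] <- data.frame(
      feature = f, value = X[, j], shap = report$shap_values[, j],
      interacting_feature = inter,
      interacting_value = if (is.na(inter)) NA_real_
                          else X[, match(inter, fn)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Explain a trained dual-branch model over supervised samples
#'
#' Attributions are computed on the flattened input window (permutation
#' sampling over `window * F` inputs), then summed per feature name
#' across window positions, so a feature like `lag1` or `roll3` gets one
#' score regardless of where in the window it enters. Background rows are
#' drawn from the supplied training samples (subsampled to at most
#' `max_background`).
#'
#' @param model A trained `dual_branch_model`.
#' @param samples Samples to explain (`supervised_set`).
#' @param background_samples Training samples serving as background
#'   (defaults to `samples`).
#' @param n_permutations Permutations per explained row.
#' @param max_background Background subsample cap.
#' @param seed Seed for sampling.
#' @return An `attribution_report` with per-feature (aggregated)
#'   attributions; `dependence` holds the triples over the last-step
#'   feature values.
#' @export
explain_model <- function(model, samples, background_samples = NULL,
                          n_permutations = 64L, max_background = 100L,
                          seed = 1L) {
  stopifnot(inherits(model, "dual_branch_model"))
  if (is.null(background_samples)) background_samples <- samples
  w <- model$window; F_n <- model$n_features
  flat <- function(set) t(vapply(set, function(s) as.vector(s$X),
                                 numeric(w * F_n)))
  Xe <- flat(samples)
  bg <- flat(background_samples)
  if (nrow(bg) > max_background) {
    guard <- stf_local_seed(seed + 1L)
    bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
    guard$restore()
  }
  f <- function(rows) {
    apply(rows, 1L, function(r) {
      predict_ensemble(model, list(X = matrix(r, w, F_n),
                                   y_hist = rep(0, w)))$y_hat
    })
  }
  fn <- model$feature_names
  if (is.null(fn)) fn <- paste0("f", seq_len(F_n))
  flat_names <- as.vector(outer(seq_len(w), fn,
                                function(t, nm) paste0(nm, "@t", t)))
  rep_flat <- shapley_attributions(f, Xe, bg,
                                   n_permutations = n_permutations,
                                   seed = seed, mode = "sampling",
                                   feature_names = flat_names)
  agg <- matrix(0, nrow(Xe), F_n, dimnames = list(NULL, fn))
  for (j in seq_len(F_n)) {
    cols <- (j - 1L) * w + seq_len(w)
    agg[, j] <- rowSums(rep_flat$shap_values[, cols, drop = FALSE])
  }
  report <- structure(list(
    shap_values = agg, base_value = rep_flat$base_value,
    feature_names = fn, method = "sampling",
    n_permutations = as.integer(n_permutations), se = NULL
  ), class = "attribution_report")
  report$importance <- importance_summary(report)
  last_step <- t(vapply(samples, function(s) s$X[w, ], numeric(F_n)))
  colnames(last_step) <- fn
  report$dependence <- shap_dependence(report, last_step)
  report
}
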