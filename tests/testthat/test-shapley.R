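additive_f <- function(w) {
  force(w)
  function(X) as.vector(as.matrix(X) %*% w)
}

test_that("exact attributions recover the closed form for additive models", {
  w <- c(2, -1, 0.5, 3)
  f <- additive_f(w)
  bg <- matrix(c(1, 1, 1, 1), 1, 4)
  X <- rbind(c(2, 0, 4, -1), c(0, 0, 0, 0))
  rep <- shapley_attributions(f, X, bg, mode = "exact")
  for (i in 1:2) {
    expect_equal(unname(rep$shap_values[i, ]), w * (X[i, ] - bg[1, ]),
                 tolerance = 1e-10)
  }
  expect_equal(rep$base_value, f(bg), tolerance = 1e-12)
})

test_that("a constant model attributes nothing", {
  f <- function(X) rep(7.5, nrow(X))
  rep <- shapley_attributions(f, matrix(rnorm(12), 3, 4),
                              matrix(rnorm(8), 2, 4), mode = "exact")
  expect_equal(unname(rep$shap_values), matrix(0, 3, 4))
  expect_equal(rep$base_value, 7.5)
})

test_that("efficiency, symmetry and dummy axioms hold in exact mode", {
  set.seed(21)
  f <- function(X) {
    X <- as.matrix(X)
    # symmetric in columns 1 and 2; ignores column 4
    X[, 1] * X[, 2] + X[, 1] + X[, 2] + 2 * X[, 3]^2
  }
  bg <- matrix(rnorm(20), 5, 4)
  X <- matrix(rnorm(12), 3, 4)
  rep <- shapley_attributions(f, X, bg, mode = "exact")
  # efficiency: base + sum of attributions = prediction
  expect_equal(rep$base_value + rowSums(rep$shap_values), f(X),
               tolerance = 1e-8)
  # dummy: ignored feature gets zero
  expect_equal(unname(rep$shap_values[, 4]), rep(0, 3), tolerance = 1e-8)
  # symmetry: interchangeable features with equal values get equal credit
  x_sym <- matrix(c(1.3, 1.3, 0.5, 2), 1, 4)
  bg_sym <- matrix(c(0.2, 0.2, -1, 1), 1, 4)
  rep_sym <- shapley_attributions(f, x_sym, bg_sym, mode = "exact")
  expect_equal(unname(rep_sym$shap_values[1, 1]),
               unname(rep_sym$shap_values[1, 2]), tolerance = 1e-8)
})

test_that("the sampling estimator converges to the exact enumeration", {
  set.seed(22)
  f <- function(X) {
    X <- as.matrix(X)
    X[, 1] * X[, 2] - 2 * X[, 3] + X[, 4]^2
  }
  bg <- matrix(rnorm(12), 3, 4)
  X <- matrix(rnorm(4), 1, 4)
  exact <- shapley_attributions(f, X, bg, mode = "exact")
  sampled <- shapley_attributions(f, X, bg, n_permutations = 5000,
                                  seed = 3, mode = "sampling")
  expect_lt(max(abs(exact$shap_values - sampled$shap_values)), 1e-2)
  # efficiency within reported Monte-Carlo error (loose multiple)
  expect_lt(abs(sampled$base_value + sum(sampled$shap_values) - f(X)),
            6 * sqrt(sum(sampled$se^2)) + 1e-3)
  # deterministic given the seed
  sampled2 <- shapley_attributions(f, X, bg, n_permutations = 5000,
                                   seed = 3, mode = "sampling")
  expect_identical(sampled$shap_values, sampled2$shap_values)
  expect_error(shapley_attributions(f, X, bg, n_permutations = 0,
                                    mode = "sampling"), "n_permutations")
})

test_that("importance ranking orders by mean |shap| with alphabetical ties", {
  w <- c(0.1, 5, 0.1, 2)
  f <- additive_f(w)
  bg <- matrix(0, 1, 4)
  X <- matrix(rep(1, 8), 2, 4, dimnames = list(NULL, c("d", "a", "b", "c")))
  rep <- shapley_attributions(f, X, bg, mode = "exact")
  expect_equal(rep$importance$feature, c("a", "c", "b", "d"))

  zero <- shapley_attributions(function(X) rep(0, nrow(X)), X, bg,
                               mode = "exact")
  expect_equal(zero$importance$feature, c("a", "b", "c", "d"))
  expect_equal(zero$importance$mean_abs_shap, rep(0, 4))
})

test_that("dependence triples pick the most correlated interacting feature", {
  set.seed(23)
  n <- 40
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, sd = 0.1); x3 <- rnorm(n)
  X <- cbind(f1 = x1, f2 = x2, f3 = x3)
  f <- function(M) as.matrix(M)[, 1] * 2
  rep <- shapley_attributions(f, X, X[1:5, ], mode = "exact")
  dep <- shap_dependence(rep, X, features = "f1")
  # f1's attributions track x1, and x2 is the most correlated other feature
  expect_equal(unique(dep$interacting_feature), "f2")
  expect_equal(nrow(dep), n)
  expect_equal(dep$value, unname(x1))
})

test_that("model explanations aggregate window positions per feature", {
  prep <- accept_prep()
  fit <- accept_fit("full", 1)
  model <- fit$model
  model$scaler <- prep[[1]]$scaler
  model$feature_names <- prep[[1]]$feature_names
  expl <- explain_model(model, prep[[1]]$splits$test[1:3],
                        background_samples = prep[[1]]$splits$train,
                        n_permutations = 16, seed = 2)
  expect_equal(colnames(expl$shap_values), prep[[1]]$feature_names)
  expect_equal(nrow(expl$shap_values), 3)
  expect_setequal(expl$importance$feature, prep[[1]]$feature_names)
  # efficiency is preserved by per-feature aggregation
  preds <- vapply(prep[[1]]$splits$test[1:3], function(s)
    predict_ensemble(model, s)$y_hat, numeric(1))
  resid <- expl$base_value + rowSums(expl$shap_values) - preds
  expect_lt(max(abs(resid)), 1e-8)  # telescoping makes efficiency exact
})
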