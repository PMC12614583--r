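test_that("the dual-branch objective is the weighted sum of branch MSEs", {
  expect_equal(dual_branch_loss(c(1, 2), c(1, 2), c(1, 2)), 0)
  expect_equal(dual_branch_loss(0, 1, 3), 10)           # 1 + 9
  expect_equal(dual_branch_loss(0, 1, 3, alpha = 1, beta = 0), 1)
  expect_equal(dual_branch_loss(c(0, 0), c(1, 3), c(3, 1)),
               dual_branch_loss(c(0, 0), c(3, 1), c(1, 3)))  # symmetric
  y <- rnorm(5); a <- rnorm(5); b <- rnorm(5)
  expect_gte(dual_branch_loss(y, a, b), 0)
  expect_equal(dual_branch_loss(y, a, b, alpha = 2, beta = 0.5),
               2 * mean((y - a)^2) + 0.5 * mean((y - b)^2),
               tolerance = 1e-12)
  expect_error(dual_branch_loss(1:3, 1:2, 1:3), "shape")
  expect_error(train_config(alpha = 0, beta = 0), "alpha")
})

test_that("configuration invariants are enforced", {
  expect_error(train_config(embedding_dim = 100, n_heads = 8), "divisible")
  tc <- train_config()
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$batch_size, 64L)
  expect_equal(tc$epochs, 100L)
  expect_equal(tc$embedding_dim, 128L)
  expect_equal(tc$n_heads, 8L)
  expect_equal(tc$ffn_dims, c(256L, 128L))
  expect_equal(tc$dropout, 0.1)
  expect_equal(tc$alpha, 1); expect_equal(tc$beta, 1)
})

tiny_samples <- function(n = 12, Fn = 3, W = 3, seed = 5) {
  set.seed(seed)
  structure(lapply(seq_len(n), function(i) {
    list(X = matrix(rnorm(W * Fn), W, Fn), y_hist = rnorm(W), y = rnorm(1))
  }), class = "supervised_set")
}

tiny_config <- function(...) {
  train_config(embedding_dim = 8, n_heads = 2, sta_heads = 2, n_layers = 1,
               sta_layers = 1, ffn_dims = c(8, 4), dropout = 0,
               batch_size = 6, window = 3, ...)
}

test_that("training is seeded-deterministic and respects epochs = 0", {
  data <- tiny_samples()
  tc <- tiny_config(epochs = 3, seed = 9)
  f1 <- train_model(data, tc)
  f2 <- train_model(data, tc)
  keep <- setdiff(names(f1$trace), "seconds")   # wall clock may differ
  expect_identical(f1$trace[keep], f2$trace[keep])
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$trace), 3L)

  f0 <- train_model(data, tiny_config(epochs = 0, seed = 9))
  expect_equal(nrow(f0$trace), 0L)
  init <- init_dual_branch_model(tiny_config(epochs = 0, seed = 9), 3, 3,
                                 constraint = f0$model$constraint)
  expect_identical(f0$model$params, init$params)
})

test_that("parameter counts match within a config and differ across arms", {
  counts <- vapply(c("transformer", "jth", "sta", "full"), function(arm) {
    init_dual_branch_model(tiny_config(epochs = 1, ablation = arm),
                           4, 3)$n_params
  }, numeric(1))
  expect_equal(length(unique(counts)), 4L)
  m1 <- init_dual_branch_model(tiny_config(epochs = 1, seed = 1), 4, 3)
  m2 <- init_dual_branch_model(tiny_config(epochs = 1, seed = 99), 4, 3)
  expect_equal(m1$n_params, m2$n_params)
})

test_that("the ensemble is the arithmetic mean of the branch outputs", {
  data <- tiny_samples()
  fit <- train_model(data, tiny_config(epochs = 2, seed = 3))
  s <- data[[1]]
  p <- predict_ensemble(fit$model, s)
  expect_equal(p$y_hat, (p$y_pred_branch + p$y_out_branch) / 2,
               tolerance = 1e-12)
  # identical branch outputs are a fixed point by construction
  expect_equal(mean(c(p$y_pred_branch, p$y_pred_branch)), p$y_pred_branch)

  fit_j <- train_model(data, tiny_config(epochs = 2, seed = 3,
                                         ablation = "jth"))
  pj <- predict_ensemble(fit_j$model, s)
  expect_equal(pj$y_hat, pj$y_pred_branch)   # single active branch
  expect_true(is.na(pj$y_out_branch))

  expect_error(predict_ensemble(fit$model, matrix(0, 2, 3)), "shape")
})

test_that("divergence is reported with the last finite epoch", {
  data <- tiny_samples()
  # layer normalization would renormalize even astronomically large
  # activations, so the blow-up is provoked without it; the step size is
  # chosen so the prediction's product of parameter scales overflows
  tc <- tiny_config(epochs = 30, seed = 3, learning_rate = 1e120,
                    use_layernorm = FALSE)
  expect_error(train_model(data, tc), "divergence|non-finite")
})

test_that("checkpoints round-trip and detect config tampering", {
  data <- tiny_samples()
  fit <- train_model(data, tiny_config(epochs = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  expect_equal(predict_ensemble(back, data[[1]]),
               predict_ensemble(fit$model, data[[1]]))
})

test_that("the full model overfits a small noiseless series", {
  # optimization sanity: 20 supervised samples from a deterministic
  # trend must be drivable to near-zero training loss
  p <- trend_panel(years = c(1995, 2023), trend = 0.5)
  # a noiseless trend has constant differences, which cannot be z-scored
  spec <- feature_spec(diff_orders = integer(0))
  fm <- zscore_normalize(build_features(p, spec))
  ss <- assemble_supervised(fm, window = 5)
  expect_equal(length(ss), 20L)  # 25 valid rows - window 5
  tc <- train_config(embedding_dim = 16, n_heads = 2, n_layers = 1,
                     sta_layers = 1, sta_heads = 2, ffn_dims = c(32, 16),
                     dropout = 0, epochs = 150, batch_size = 8, seed = 1,
                     window = 5, learning_rate = 3e-3,
                     use_layernorm = FALSE)
  fit <- fixture("overfit_fit", function() train_model(ss, tc))
  expect_lt(min(fit$trace$loss), 1e-2)
  expect_true(all(is.finite(fit$trace$loss)))
})

test_that("training loss decreases and branch losses are recorded", {
  data <- tiny_samples(n = 16)
  fit <- train_model(data, tiny_config(epochs = 15, seed = 2,
                                       learning_rate = 5e-3),
                     validation = unclass(tiny_samples(n = 4, seed = 6)))
  expect_lt(tail(fit$trace$loss, 1), fit$trace$loss[1])
  expect_true(all(is.finite(fit$trace$loss_jth)))
  expect_true(all(is.finite(fit$trace$loss_sta)))
  expect_true(all(is.finite(fit$trace$val_mse)))
  expect_equal(nrow(fit$trace), 15L)
})
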