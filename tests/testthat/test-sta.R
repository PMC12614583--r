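toy_sta_params <- function(d, n_heads = 1L, seed = 1L) {
  set.seed(seed)
  list(Wq = matrix(rnorm(d * d, sd = 0.4), d, d),
       Wk = matrix(rnorm(d * d, sd = 0.4), d, d),
       Wv = matrix(rnorm(d * d, sd = 0.4), d, d),
       Wo = diag(d), n_heads = n_heads)
}

uniform_constraint <- function(S) {
  staforecast:::stf_uniform_constraint(S, learnable = FALSE)
}

# independent loop-based oracle for the jointly constrained attention
sta_oracle <- function(U, omega, phi, params) {
  d3 <- dim(U); T_len <- d3[1]; S <- d3[2]; d <- d3[3]
  Uf <- matrix(0, T_len * S, d)
  for (t in seq_len(T_len)) for (s in seq_len(S)) {
    Uf[(t - 1) * S + s, ] <- U[t, s, ]
  }
  Q <- Uf %*% params$Wq; K <- Uf %*% params$Wk; V <- Uf %*% params$Wv
  n <- T_len * S
  beta <- matrix(0, n, n)
  Vc <- matrix(0, n, d)
  for (i in seq_len(n)) {
    ti <- (i - 1) %/% S + 1; si <- (i - 1) %% S + 1
    logits <- numeric(n)
    for (j in seq_len(n)) {
      tj <- (j - 1) %/% S + 1; sj <- (j - 1) %% S + 1
      psi <- sum(Q[i, ] * K[j, ]) / sqrt(d)
      logits[j] <- psi * omega[ti, tj] * phi[si, sj]
    }
    w <- exp(logits - max(logits)); w <- w / sum(w)
    beta[i, ] <- w
    for (j in seq_len(n)) Vc[i, ] <- Vc[i, ] + w[j] * V[j, ]
  }
  list(beta = beta, V = Vc %*% params$Wo)
}

test_that("the decay kernel matches its closed forms", {
  k <- temporal_decay(6, lambda_t = 2)
  expect_equal(diag(k$omega), rep(1, 6))
  expect_equal(k$omega[1, 3], exp(-1), tolerance = 1e-12)  # |t - tau| = lambda
  expect_true(isSymmetric(k$omega))
  # strictly decreasing in lag
  lags <- abs(outer(1:6, 1:6, "-"))
  for (l in 1:4) {
    expect_true(all(k$omega[lags == l] > k$omega[lags == l + 1][1]))
  }
  # infinite scale recovers unconstrained attention
  expect_equal(temporal_decay(5, Inf)$omega, matrix(1, 5, 5))
  expect_error(temporal_decay(5, 0), "lambda_t")
  expect_error(temporal_decay(5, -2), "lambda_t")
})

test_that("correlation constraint matches an independent Pearson oracle", {
  set.seed(8)
  X <- cbind(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  X[, 2] <- 0.8 * X[, 1] + 0.2 * X[, 2]
  con <- spatial_constraint_from_correlation(X, learnable = FALSE)
  A_oracle <- abs(stats::cor(X))
  phi_oracle <- A_oracle / rowSums(A_oracle)
  expect_equal(con$phi, phi_oracle, tolerance = 1e-10)
  expect_equal(unname(rowSums(con$phi)), rep(1, 3), tolerance = 1e-12)
  # diagonal dominates its row (self-correlation is 1)
  expect_true(all(diag(con$A_raw) >= apply(con$A_raw, 1, max) - 1e-12))

  # two perfectly correlated features -> uniform 2 x 2 constraint
  Y <- cbind(rnorm(20))
  Y <- cbind(Y, 2 * Y[, 1])
  con2 <- spatial_constraint_from_correlation(Y, learnable = FALSE)
  expect_equal(con2$phi, matrix(0.5, 2, 2), tolerance = 1e-12)

  expect_error(spatial_constraint_from_correlation(X[1:2, ]),
               "insufficient data")
})

test_that("constant feature columns receive a uniform association row", {
  X <- cbind(rnorm(20), rep(3, 20), rnorm(20))
  con <- spatial_constraint_from_correlation(X, learnable = FALSE)
  expect_equal(con$phi[2, ], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(rowSums(con$phi), rep(1, 3), tolerance = 1e-12)
})

test_that("constrained attention rows live on the simplex", {
  set.seed(9)
  for (i in 1:5) {
    T_len <- sample(2:4, 1); S <- sample(2:4, 1); d <- 4
    U <- array(rnorm(T_len * S * d), c(T_len, S, d))
    out <- sta_attention_forward(U, temporal_decay(T_len, 2),
                                 uniform_constraint(S), toy_sta_params(d))
    expect_equal(rowSums(out$beta[1, , ]), rep(1, T_len * S),
                 tolerance = 1e-6)
    expect_true(all(out$beta >= 0))
  }
})

test_that("identical tokens under a flat constraint give uniform weights", {
  T_len <- 3; S <- 2; d <- 4
  u <- rnorm(d)
  U <- array(rep(u, each = T_len * S), c(T_len, S, d))
  out <- sta_attention_forward(U, temporal_decay(T_len, Inf),
                               uniform_constraint(S), toy_sta_params(d))
  expect_equal(out$beta[1, , ], matrix(1 / 6, 6, 6), tolerance = 1e-10)
})

test_that("constrained attention matches the exhaustive dense oracle", {
  set.seed(10)
  for (T_len in 2:4) for (S in 2:4) {
    d <- 4
    U <- array(rnorm(T_len * S * d), c(T_len, S, d))
    kernel <- temporal_decay(T_len, T_len / 2)
    X <- matrix(rnorm(12 * S), 12, S)
    con <- spatial_constraint_from_correlation(X, learnable = FALSE)
    params <- toy_sta_params(d, seed = T_len * 10 + S)
    params$scale <- "full"
    out <- sta_attention_forward(U, kernel, con, params)
    oracle <- sta_oracle(U, kernel$omega, con$phi, params)
    expect_equal(out$beta[1, , ], oracle$beta, tolerance = 1e-8)
    expect_equal(matrix(aperm(out$V_ctx, c(2, 1, 3)), T_len * S, d),
                 oracle$V, tolerance = 1e-8)
  }
})

test_that("additive constraint with uniform associations is plain attention", {
  # log-space bias by a constant (uniform phi, omega = 1) cancels in the
  # softmax, recovering unconstrained joint attention exactly
  T_len <- 3; S <- 3; d <- 4
  set.seed(12)
  U <- array(rnorm(T_len * S * d), c(T_len, S, d))
  params <- toy_sta_params(d)
  out <- sta_attention_forward(U, temporal_decay(T_len, Inf),
                               uniform_constraint(S), params,
                               mode = "additive")
  Uf <- staforecast:::stf_flatten_tokens(U)
  plain <- staforecast:::stf_mha(
    staforecast:::ad_const(Uf), staforecast:::ad_const(params$Wq),
    staforecast:::ad_const(params$Wk), staforecast:::ad_const(params$Wv),
    staforecast:::ad_const(params$Wo), 1L, d)
  expect_equal(out$beta[1, , ], plain$weights[[1]], tolerance = 1e-10)
})

test_that("spatial pooling uses softmax weights over feature positions", {
  d <- 4; T_len <- 3
  head <- toy_jth_params(2, d)$head
  V1 <- array(rnorm(T_len * 1 * d), c(T_len, 1, d))
  out1 <- sta_pool_predict(V1, eta = 5, head)
  expect_equal(out1$g_seq, matrix(V1[, 1, ], T_len, d))

  V2 <- array(rnorm(T_len * 2 * d), c(T_len, 2, d))
  out_eq <- sta_pool_predict(V2, eta = c(1, 1), head)
  expect_equal(out_eq$pool_weights, c(0.5, 0.5))
  expect_equal(out_eq$g_seq, (V2[, 1, ] + V2[, 2, ]) / 2)

  out_l3 <- sta_pool_predict(V2, eta = c(log(3), 0), head)
  expect_equal(out_l3$pool_weights, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(out_l3$g_seq, 0.75 * V2[, 1, ] + 0.25 * V2[, 2, ])
  expect_equal(out_l3$z, colMeans(out_l3$g_seq))
  expect_error(sta_pool_predict(V2, eta = c(1, 2, 3), head), "eta")
})

test_that("phi stays on the simplex through gradient refinement", {
  set.seed(13)
  samples <- lapply(1:12, function(i) {
    list(X = matrix(rnorm(12), 3, 4), y_hist = rnorm(3), y = rnorm(1))
  })
  tc <- train_config(embedding_dim = 8, n_heads = 2, sta_heads = 2,
                     n_layers = 1, sta_layers = 1, ffn_dims = c(8, 4),
                     dropout = 0, epochs = 25, batch_size = 3, seed = 4,
                     window = 3, learning_rate = 0.02, ablation = "sta",
                     learnable_constraint = TRUE)
  fit <- train_model(structure(samples, class = "supervised_set"), tc)
  A0 <- fit$model$constraint$A_free
  A1 <- fit$model$params$sta$Afree
  expect_false(identical(A0, A1))   # gradient actually reached A
  ns <- asNamespace("staforecast")
  phi <- ns$ad_rownorm(ns$ad_softplus(ns$ad_const(A1)))$val
  expect_equal(rowSums(phi), rep(1, 4), tolerance = 1e-9)
  expect_true(all(phi >= 0))
})
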