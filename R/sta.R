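# Spatiotemporally constrained attention (STA). "Spatial" positions are
# feature dimensions, not geographic neighbors: token (t, s) is a
# d-dimensional embedding of feature s's value at time step t. Attention
# logits between tokens are modulated by (i) an exponential temporal decay
# kernel omega[t, tau] = exp(-|t - tau| / lambda_t) and (ii) a
# row-normalized feature-association matrix phi built from absolute
# Pearson correlations between feature columns (optionally refined by
# gradient through a softplus reparameterization). The constraint
# multiplies the scaled similarity inside the softmax exponential;
# an additive log-space variant is available.

#' Exponential temporal decay kernel
#'
#' `omega[t, tau] = exp(-|t - tau| / lambda_t)`. Larger `lambda_t` means
#' slower decay; as `lambda_t -> Inf` the kernel tends to 1 everywhere and
#' unconstrained attention is recovered.
#'
#' @param T_len Number of time steps.
#' @param lambda_t Positive temporal scale, in time steps.
#' @return A `decay_kernel` list with `omega` (`T x T`, symmetric, unit
#'   diagonal, strictly decreasing in `|t - tau|`) and `lambda_t`.
#' @export
temporal_decay <- function(T_len, lambda_t) {
  if (!is.numeric(lambda_t) || length(lambda_t) != 1L || !is.finite(lambda_t) &&
      !identical(lambda_t, Inf)) {
    stop("configuration error: `lambda_t` must be a positive scalar",
         call. = FALSE)
  }
  if (lambda_t <= 0) {
    stop("configuration error: `lambda_t` must be > 0", call. = FALSE)
  }
  idx <- seq_len(T_len)
  omega <- exp(-abs(outer(idx, idx, "-")) / lambda_t)
  structure(list(omega = omega, lambda_t = lambda_t), class = "decay_kernel")
}

#' Feature-association constraint matrix from correlations
#'
#' Builds `A[s, r] = |cor(feature s, feature r)|` over the supplied
#' training rows and row-normalizes it to the simplex:
#' `phi[s, r] = A[s, r] / sum_j A[s, j]`. The signs of the correlations
#' are kept as diagnostics. A constant column receives a uniform
#' association row. When `learnable`, the correlations seed free
#' parameters through an inverse-softplus so that gradient refinement
#' keeps associations non-negative and `phi` can be re-normalized on
#' every forward pass.
#'
#' @param feature_rows `T x S` matrix of feature values on training rows
#'   (`T >= 3`).
#' @param learnable Seed free parameters for gradient refinement?
#' @return A `spatial_constraint` list: `A_raw`, `phi`, `sign`,
#'   `learnable`, and `A_free` when learnable.
#' @export
spatial_constraint_from_correlation <- function(feature_rows, learnable = TRUE) {
  feature_rows <- as.matrix(feature_rows)
  if (nrow(feature_rows) < 3L) {
    stop("insufficient data: need at least 3 training rows for correlations",
         call. = FALSE)
  }
  S <- ncol(feature_rows)
  cm <- suppressWarnings(stats::cor(feature_rows))
  A <- abs(cm)
  sgn <- sign(cm)
  const_col <- apply(feature_rows, 2L, function(v) stats::sd(v) == 0)
  for (s in which(const_col)) {
    A[s, ] <- 1    # uniform association for a degenerate feature
    A[, s][!const_col] <- 0
    A[s, s] <- 1
    sgn[s, ] <- 0; sgn[, s] <- 0
  }
  A[is.na(A)] <- 1 / S
  diag(A) <- pmax(diag(A), apply(A, 1L, max))
  phi <- A / rowSums(A)
  out <- list(A_raw = A, phi = phi, sign = sgn, learnable = isTRUE(learnable))
  if (out$learnable) {
    # inverse softplus; clamp so zero correlations stay representable
    out$A_free <- log(expm1(pmax(A, 1e-3)))
  }
  structure(out, class = "spatial_constraint")
}

# row-normalized phi from a constraint (softplus path when learnable)
stf_phi_node <- function(constraint, A_free_node = NULL) {
  if (constraint$learnable && !is.null(A_free_node)) {
    ad_rownorm(ad_softplus(A_free_node))
  } else {
    ad_const(constraint$phi)
  }
}

stf_flatten_tokens <- function(U) {
  stopifnot(length(dim(U)) == 3L)
  d3 <- dim(U)
  matrix(aperm(U, c(2L, 1L, 3L)), d3[1] * d3[2], d3[3])
}

stf_unflatten_tokens <- function(M, T_len, S) {
  aperm(array(M, c(S, T_len, ncol(M))), c(2L, 1L, 3L))
}

#' Jointly constrained attention over (time, feature) tokens
#'
#' Computes scaled dot-product similarities between all token pairs,
#' modulates them with `omega[t, tau] * phi[s, r]`, applies one softmax
#' jointly over all `(tau, r)`, and aggregates value projections:
#' `v_{t,s} = sum_{tau,r} beta[(t,s),(tau,r)] (W_V u_{tau,r})`.
#'
#' @param U `T x S x d` array of token representations.
#' @param kernel A [temporal_decay()] kernel with matching `T`.
#' @param constraint A [spatial_constraint_from_correlation()] object with
#'   matching `S`.
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`); optional
#'   `n_heads` (default 1, the strict single-head mode) and
#'   `scale` (`"per_head"` or `"full"`).
#' @param mode Constraint placement: `"multiplicative"` (inside the
#'   exponential, as the attention weights are defined) or `"additive"`
#'   (log-space bias).
#' @return List with `V_ctx` (`T x S x d` context array) and `beta`
#'   (`n_heads x (T S) x (T S)` row-stochastic weights; token order is
#'   feature-fastest within time).
#' @export
sta_attention_forward <- function(U, kernel, constraint, params,
                                  mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  d3 <- dim(U)
  T_len <- d3[1]; S <- d3[2]; d <- d3[3]
  if (nrow(kernel$omega) != T_len) {
    stop("shape error: kernel T does not match U", call. = FALSE)
  }
  if (nrow(constraint$phi) != S) {
    stop("shape error: constraint S does not match U", call. = FALSE)
  }
  n_heads <- if (is.null(params$n_heads)) 1L else params$n_heads
  scale <- if (is.null(params$scale)) "per_head" else params$scale
  scale_dim <- if (scale == "per_head") d %/% n_heads else d
  W <- kronecker(kernel$omega, constraint$phi)
  Uflat <- stf_flatten_tokens(U)
  out <- stf_mha(ad_const(Uflat), ad_const(params$Wq), ad_const(params$Wk),
                 ad_const(params$Wv), ad_const(params$Wo), n_heads, scale_dim,
                 constraint = ad_const(W), mode = mode)
  ts <- T_len * S
  beta <- array(0, c(n_heads, ts, ts))
  for (h in seq_len(n_heads)) beta[h, , ] <- out$weights[[h]]
  list(V_ctx = stf_unflatten_tokens(out$Z$val, T_len, S), beta = beta)
}

#' Learnable spatial pooling and spatiotemporal prediction
#'
#' The learnable spatial weights `eta` are passed through a softmax so the
#' pooled combination lies on the simplex: `g_t = sum_s softmax(eta)_s
#' v_{t,s}`. The sequence is aggregated by temporal mean pooling,
#' `z = mean_t g_t`, and the feed-forward head produces the
#' spatiotemporal-branch prediction.
#'
#' @param V_ctx `T x S x d` context array from [sta_attention_forward()].
#' @param eta Length-S numeric vector of unnormalized spatial weights.
#' @param params Head parameters (`W1`, `b1`, `W2`, `b2`, `Wo`, `bo`).
#' @return List with `g_seq` (`T x d`), `z` (length d), `y_hat_out`
#'   (scalar), and `pool_weights` (the softmax of `eta`).
#' @export
sta_pool_predict <- function(V_ctx, eta, params) {
  d3 <- dim(V_ctx)
  T_len <- d3[1]; S <- d3[2]
  if (length(eta) != S) {
    stop("shape error: `eta` length must equal the number of feature positions",
         call. = FALSE)
  }
  w <- exp(eta - max(eta)); w <- w / sum(w)
  g_seq <- matrix(0, T_len, d3[3])
  for (s in seq_len(S)) g_seq <- g_seq + w[s] * V_ctx[, s, , drop = TRUE]
  if (T_len == 1L) g_seq <- matrix(g_seq, 1L)
  z <- colMeans(g_seq)
  y <- stf_head(ad_const(matrix(z, 1L)), lapply(params, ad_const),
                dropout = 0, training = FALSE)
  list(g_seq = g_seq, z = z, y_hat_out = y$val[1L, 1L], pool_weights = w)
}

# training-time forward of the spatiotemporal branch for a stacked
# minibatch: x_stack is (B * T) x S; tokens are expanded to
# (B * T * S) x d with feature index fastest. The omega (x) phi
# constraint is built once per pass and shared by every sample block, so
# gradient flows into the learnable association matrix from the whole
# batch. Returns a B x 1 prediction node.
stf_sta_branch_batch <- function(x_stack, P, cfg, constraint, B, T_len,
                                 training) {
  S <- ncol(x_stack)
  d <- ncol(P$Wlift$val)
  n_tok <- B * T_len * S
  pat <- stf_cached(sprintf("stapat_%d_%d_%d_%d", B, T_len, S, d), function() {
    colpat <- rep(seq_len(S), B * T_len)
    Ind <- matrix(0, n_tok, S)
    Ind[cbind(seq_len(n_tok), colpat)] <- 1
    pe <- sinusoidal_encoding(T_len, d)[rep(rep(seq_len(T_len), each = S), B),
                                        , drop = FALSE]
    list(colpat = colpat, Ind = Ind, pe = pe)
  })
  D <- matrix(0, n_tok, S)
  D[cbind(seq_len(n_tok), pat$colpat)] <- as.vector(t(x_stack))
  U <- ad_add(ad_add(ad_matmul(ad_const(D), P$Wlift),
                     ad_matmul(ad_const(pat$Ind), P$Blift)),
              ad_const(pat$pe))

  lambda <- if (is.null(cfg$lambda_t)) T_len / 2 else cfg$lambda_t
  omega <- temporal_decay(T_len, lambda)$omega
  phi <- stf_phi_node(constraint, P$Afree)
  W <- if (constraint$learnable) ad_kron(omega, phi)
       else ad_const(kronecker(omega, constraint$phi))

  scale_dim <- if (cfg$attn_scale == "per_head") d %/% cfg$sta_heads else d
  for (lp in P$layers) {
    U <- stf_encoder_layer_blocks(U, lp, cfg$sta_heads, scale_dim, B,
                                  T_len * S, cfg$dropout, training,
                                  use_layernorm = cfg$use_layernorm,
                                  use_ffn = FALSE, constraint = W,
                                  mode = cfg$constraint_mode)
  }
  # learnable spatial pooling: g_{b,t} = sum_s softmax(eta)_s u_{b,t,s}
  wpool <- ad_softmax_rows(P$eta)
  terms <- lapply(seq_len(S), function(s) {
    ad_scale_node(ad_rows(U, seq(s, n_tok, by = S)), ad_cols(wpool, s))
  })
  G <- ad_add_list(terms)                         # (B T) x d pooled sequence
  z <- ad_matmul(ad_const(stf_pool_matrix(B, T_len)), G)  # temporal mean
  stf_head(z, P$head, cfg$dropout, training)
}
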