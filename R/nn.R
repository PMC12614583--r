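# Shared neural building blocks: parameter initialization, sinusoidal
# positional encodings, multi-head attention, encoder sub-layers, and the
# feed-forward prediction head. Everything operates on autodiff nodes so
# the same forward code serves training (with gradients) and inference.

stf_glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

stf_zeros <- function(n_in, n_out = NULL) {
  if (is.null(n_out)) matrix(0, 1L, n_in) else matrix(0, n_in, n_out)
}

#' Sinusoidal positional encoding
#'
#' The closed-form encoding
#' `PE[t, 2i] = sin(t / 10000^(2i/d))`, `PE[t, 2i+1] = cos(t / 10000^(2i/d))`
#' with zero-based time index and column pairs `i = 0 .. d/2 - 1`. Being a
#' deterministic function of `t`, it extrapolates consistently to time
#' steps never seen in training.
#'
#' @param T_len Number of time steps to encode.
#' @param d Embedding dimension (must be even).
#' @param t0 Zero-based index of the first row's time step.
#' @return A `T_len x d` matrix with entries in `[-1, 1]`.
#' @export
sinusoidal_encoding <- function(T_len, d, t0 = 0) {
  if (d %% 2L != 0L) {
    stop("configuration error: embedding dimension `d` must be even",
         call. = FALSE)
  }
  key <- sprintf("%d_%d_%g", T_len, d, t0)
  hit <- .stf_pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- t0 + seq_len(T_len) - 1
  i <- seq_len(d %/% 2L) - 1
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(t, freq)
  pe <- matrix(0, T_len, d)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  .stf_pe_cache[[key]] <- pe
  pe
}

.stf_pe_cache <- new.env(parent = emptyenv())

# dropout mask as a constant node factor; identity when not training
stf_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- matrix(stats::rbinom(length(x$val), 1L, 1 - p) / (1 - p),
                 nrow(x$val), ncol(x$val))
  ad_mul(x, ad_const(mask))
}

# Multi-head scaled-dot-product self-attention over token rows.
# `constraint` (optional node or NULL) multiplies the scaled scores inside
# the exponential when mode = "multiplicative", or its log is added to them
# when mode = "additive". Returns the mixed output and per-head weights.
stf_mha <- function(X, Wq, Wk, Wv, Wo, n_heads, scale_dim,
                    constraint = NULL, mode = "multiplicative") {
  d <- ncol(X$val)
  dh <- d %/% n_heads
  Q <- ad_matmul(X, Wq); K <- ad_matmul(X, Wk); V <- ad_matmul(X, Wv)
  outs <- vector("list", n_heads)
  weights <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    psi <- ad_scale(ad_matmul_tb(ad_cols(Q, idx), ad_cols(K, idx)),
                    1 / sqrt(scale_dim))
    logits <- if (is.null(constraint)) psi
      else if (mode == "multiplicative") ad_mul(psi, constraint)
      else ad_add(psi, ad_log(constraint))
    P <- ad_softmax_rows(logits)
    weights[[h]] <- P$val
    outs[[h]] <- ad_matmul(P, ad_cols(V, idx))
  }
  Z <- ad_matmul(ad_cbind(outs), Wo)
  list(Z = Z, weights = weights)
}

# two hidden layers (ReLU, dropout) then linear to scalar
stf_head <- function(g, hp, dropout, training) {
  h1 <- ad_relu(ad_add_bias(ad_matmul(g, hp$W1), hp$b1))
  h1 <- stf_dropout(h1, dropout, training)
  h2 <- ad_relu(ad_add_bias(ad_matmul(h1, hp$W2), hp$b2))
  h2 <- stf_dropout(h2, dropout, training)
  ad_add_bias(ad_matmul(h2, hp$Wo), hp$bo)
}

# Block-diagonal multi-head self-attention for a stacked minibatch:
# B independent samples of `block_len` tokens each are stacked in rows;
# attention never crosses sample blocks, so projections, feed-forward and
# normalization run batched while softmax attention runs per block.
# `constraint` is an optional (block_len x block_len) node shared by all
# blocks (the decay-kernel x association-matrix modulation).
stf_mha_blocks <- function(X, lp, n_heads, scale_dim, B, block_len,
                           constraint = NULL, mode = "multiplicative") {
  d <- ncol(X$val)
  dh <- d %/% n_heads
  Q <- ad_matmul(X, lp$Wq); K <- ad_matmul(X, lp$Wk); V <- ad_matmul(X, lp$Wv)
  logW <- if (!is.null(constraint) && mode == "additive") ad_log(constraint)
          else NULL
  head_parts <- replicate(n_heads, vector("list", B), simplify = FALSE)
  for (b in seq_len(B)) {
    idx <- (b - 1L) * block_len + seq_len(block_len)
    Qb <- ad_rows(Q, idx); Kb <- ad_rows(K, idx); Vb <- ad_rows(V, idx)
    for (h in seq_len(n_heads)) {
      cidx <- (h - 1L) * dh + seq_len(dh)
      psi <- ad_scale(ad_matmul_tb(ad_cols(Qb, cidx), ad_cols(Kb, cidx)),
                      1 / sqrt(scale_dim))
      logits <- if (is.null(constraint)) psi
        else if (mode == "multiplicative") ad_mul(psi, constraint)
        else ad_add(psi, logW)
      P <- ad_softmax_rows(logits)
      head_parts[[h]][[b]] <- ad_matmul(P, ad_cols(Vb, cidx))
    }
  }
  ad_matmul(ad_cbind(lapply(head_parts, ad_rbind)), lp$Wo)
}

stf_encoder_layer_blocks <- function(X, lp, n_heads, scale_dim, B, block_len,
                                     dropout, training, use_layernorm = TRUE,
                                     use_ffn = TRUE, constraint = NULL,
                                     mode = "multiplicative") {
  Z <- stf_mha_blocks(X, lp, n_heads, scale_dim, B, block_len,
                      constraint = constraint, mode = mode)
  Z <- stf_dropout(Z, dropout, training)
  H <- ad_add(X, Z)
  if (use_layernorm) H <- ad_layernorm(H, lp$ln1g, lp$ln1b)
  if (use_ffn) {
    Fh <- ad_relu(ad_add_bias(ad_matmul(H, lp$W1), lp$b1))
    Fh <- stf_dropout(Fh, dropout, training)
    Fo <- ad_add_bias(ad_matmul(Fh, lp$W2), lp$b2)
    H2 <- ad_add(H, Fo)
    if (use_layernorm) H2 <- ad_layernorm(H2, lp$ln2g, lp$ln2b)
    H <- H2
  }
  H
}

.stf_cache <- new.env(parent = emptyenv())

stf_cached <- function(key, build) {
  hit <- .stf_cache[[key]]
  if (!is.null(hit)) return(hit)
  .stf_cache[[key]] <- build()
  .stf_cache[[key]]
}

# B x (B * block_len) block-mean pooling operator
stf_pool_matrix <- function(B, block_len) {
  stf_cached(sprintf("pool_%d_%d", B, block_len), function() {
    P <- matrix(0, B, B * block_len)
    for (b in seq_len(B)) {
      P[b, (b - 1L) * block_len + seq_len(block_len)] <- 1 / block_len
    }
    P
  })
}

stf_init_layer <- function(d, ffn_hidden) {
  list(Wq = stf_glorot(d, d), Wk = stf_glorot(d, d), Wv = stf_glorot(d, d),
       Wo = stf_glorot(d, d),
       ln1g = matrix(1, 1L, d), ln1b = stf_zeros(d),
       W1 = stf_glorot(d, ffn_hidden), b1 = stf_zeros(ffn_hidden),
       W2 = stf_glorot(ffn_hidden, d), b2 = stf_zeros(d),
       ln2g = matrix(1, 1L, d), ln2b = stf_zeros(d))
}

stf_init_head <- function(d, h1, h2) {
  list(W1 = stf_glorot(d, h1), b1 = stf_zeros(h1),
       W2 = stf_glorot(h1, h2), b2 = stf_zeros(h2),
       Wo = stf_glorot(h2, 1L), bo = stf_zeros(1L))
}

# flatten a nested list of matrices into "path"-named entries
stf_flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) out <- c(out, stf_flatten_params(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}
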