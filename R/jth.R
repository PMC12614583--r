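# Joint temporal-health encoding (JTH): each time step's engineered
# feature row is linearly projected into a d-dimensional latent space and
# combined, by addition, with a sinusoidal encoding of the time index.
# Multi-head temporal self-attention with a residual connection then mixes
# information across time steps, the per-step representations are pooled,
# and a feed-forward head maps the pooled vector to the next-step
# prevalence. These exported operations expose the core mapping on plain
# matrices; the trained model composes the same pieces (plus layer
# normalization and position-wise feed-forward sub-layers) on the
# autodiff tape.

#' Embed a feature window into the latent space
#'
#' Computes `h_t = x_t W_in + b_in + PE[t]`: a learned linear projection of
#' the time step's feature row plus the sinusoidal positional encoding.
#' The same projection weights apply at every time step.
#'
#' @param x `T x F` matrix of feature rows (no masked rows).
#' @param params Branch parameters with `Win` (`F x d`) and `bin` (`1 x d`),
#'   e.g. `model$params$jth` from [init_dual_branch_model()].
#' @param t0 Zero-based time index of the first row (window offset).
#' @return `T x d` matrix of per-step representations.
#' @export
embed_sequence <- function(x, params, t0 = 0) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$Win)) {
    stop(sprintf("shape error: input has %d features but projection expects %d",
                 ncol(x), nrow(params$Win)), call. = FALSE)
  }
  d <- ncol(params$Win)
  H <- sweep(x %*% params$Win, 2L, as.vector(params$bin), "+")
  H + sinusoidal_encoding(nrow(x), d, t0 = t0)
}

#' Multi-head temporal self-attention
#'
#' Per head, `Q = H W_Q`, `K = H W_K`, `V = H W_V`;
#' `alpha[t, tau] = softmax_tau(Q_t . K_tau / sqrt(d_scale))`;
#' `z_t = sum_tau alpha[t, tau] V_tau`. Head outputs are concatenated and
#' linearly mixed back to dimension d. By default the softmax temperature
#' uses the per-head sub-dimension; set `scale = "full"` for the literal
#' `sqrt(d)` reading.
#'
#' @param H `T x d` matrix of embedded time steps.
#' @param params Layer parameters with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`).
#' @param n_heads Number of attention heads (`d` divisible by it).
#' @param scale `"per_head"` or `"full"`.
#' @return List with `Z` (`T x d` context) and `alpha`
#'   (`n_heads x T x T` array of row-stochastic weights).
#' @export
temporal_self_attention <- function(H, params, n_heads = 1L,
                                    scale = c("per_head", "full")) {
  scale <- match.arg(scale)
  H <- as.matrix(H)
  d <- ncol(H)
  if (d %% n_heads != 0L) {
    stop("configuration error: d must be divisible by n_heads", call. = FALSE)
  }
  scale_dim <- if (scale == "per_head") d %/% n_heads else d
  out <- stf_mha(ad_const(H), ad_const(params$Wq), ad_const(params$Wk),
                 ad_const(params$Wv), ad_const(params$Wo),
                 n_heads, scale_dim)
  tn <- nrow(H)
  alpha <- array(0, c(n_heads, tn, tn))
  for (h in seq_len(n_heads)) alpha[h, , ] <- out$weights[[h]]
  list(Z = out$Z$val, alpha = alpha)
}

#' Temporal-branch forward pass: residual, aggregate, predict
#'
#' Applies [temporal_self_attention()], the temporal residual connection
#' `H_tilde = H + Z`, aggregation over time (mean pooling by default,
#' last-step pooling via `aggregate = "last"`), and the two-layer
#' feed-forward prediction head.
#'
#' @param H `T x d` matrix of embedded time steps.
#' @param params Branch parameters with `layers` (list of attention-layer
#'   parameter sets; the first is used here) and `head`.
#' @param n_heads Number of attention heads.
#' @param aggregate `"mean"` or `"last"`.
#' @param scale Softmax temperature convention, see
#'   [temporal_self_attention()].
#' @return List with `H_tilde` (`T x d`), `g` (length-d aggregate),
#'   `y_hat_pred` (scalar), and `alpha`.
#' @export
jth_forward <- function(H, params, n_heads = 1L,
                        aggregate = c("mean", "last"),
                        scale = c("per_head", "full")) {
  aggregate <- match.arg(aggregate)
  H <- as.matrix(H)
  att <- temporal_self_attention(H, params$layers[[1L]], n_heads = n_heads,
                                 scale = scale)
  H_tilde <- H + att$Z
  g <- if (aggregate == "mean") colMeans(H_tilde) else H_tilde[nrow(H_tilde), ]
  gn <- matrix(g, 1L)
  y <- stf_head(ad_const(gn), lapply(params$head, ad_const),
                dropout = 0, training = FALSE)
  list(H_tilde = H_tilde, g = g, y_hat_pred = y$val[1L, 1L], alpha = att$alpha)
}

# training-time forward of the temporal branch for a stacked minibatch:
# x_stack is (B * T) x F_in with B samples' windows stacked in rows;
# P holds the wrapped parameter nodes. Returns a B x 1 prediction node.
stf_jth_branch_batch <- function(x_stack, P, cfg, B, T_len, training) {
  d <- ncol(P$Win$val)
  pe <- stf_cached(sprintf("petile_%d_%d_%d", B, T_len, d), function() {
    sinusoidal_encoding(T_len, d)[rep(seq_len(T_len), B), , drop = FALSE]
  })
  H <- ad_add(ad_add_bias(ad_matmul(ad_const(x_stack), P$Win), P$bin),
              ad_const(pe))
  scale_dim <- if (cfg$attn_scale == "per_head") d %/% cfg$n_heads else d
  for (lp in P$layers) {
    H <- stf_encoder_layer_blocks(H, lp, cfg$n_heads, scale_dim, B, T_len,
                                  cfg$dropout, training,
                                  use_layernorm = cfg$use_layernorm,
                                  use_ffn = cfg$use_ffn)
  }
  g <- if (cfg$aggregate == "mean") {
    ad_matmul(ad_const(stf_pool_matrix(B, T_len)), H)
  } else {
    ad_rows(H, seq(T_len, B * T_len, by = T_len))
  }
  stf_head(g, P$head, cfg$dropout, training)
}
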