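# Dual-branch consistency training: both branches are optimized jointly
# with Adam on the weighted MSE objective
#   L = alpha * MSE(y, y_pred) + beta * MSE(y, y_out),  alpha = beta = 1,
# and inference averages the two branch predictions. All randomness
# (initialization, batch order, dropout) flows from config$seed.

#' Training configuration
#'
#' Defaults follow the reference hyperparameter table: learning rate
#' 0.001, batch size 64, 100 epochs, embedding dimension 128, 8 attention
#' heads (16 dimensions per head), 2 attention layers, feed-forward
#' dimensions 256 and 128 with ReLU, dropout 0.1, Adam, MSE loss, and
#' equal branch weights alpha = beta = 1.
#'
#' @param learning_rate Adam step size (fixed; no schedule).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training samples.
#' @param embedding_dim Latent dimension d, divisible by `n_heads`.
#' @param n_heads Attention heads of the temporal branch.
#' @param n_layers Stacked encoder layers of the temporal branch.
#' @param ffn_dims Hidden sizes of the feed-forward sub-layer and head.
#' @param dropout Dropout rate, applied in training mode only.
#' @param alpha,beta Non-negative loss weights of the temporal and
#'   spatiotemporal branches; their sum must be positive.
#' @param seed Integer seed controlling all randomness.
#' @param ablation One of `"transformer"`, `"jth"`, `"sta"`, `"full"`.
#' @param window Input window length for supervised samples.
#' @param aggregate Temporal pooling of the JTH branch, `"mean"` or
#'   `"last"`.
#' @param attn_scale Softmax temperature convention: `"per_head"` uses
#'   `sqrt(d / n_heads)`, `"full"` the literal `sqrt(d)`.
#' @param use_layernorm Layer normalization after the attention and
#'   feed-forward sub-layers (post-norm placement).
#' @param use_ffn Position-wise feed-forward sub-layer in the temporal
#'   branch's encoder layers.
#' @param sta_heads Attention heads of the STA branch (default
#'   `n_heads`; set 1 for the strict single-head reading).
#' @param sta_layers Stacked constrained-attention layers (default
#'   `n_layers`).
#' @param lambda_t Temporal decay scale; `NULL` means `window / 2`.
#' @param learnable_constraint Refine the correlation-seeded association
#'   matrix by gradient?
#' @param constraint_mode `"multiplicative"` (constraint multiplies the
#'   scaled similarity inside the softmax exponential) or `"additive"`
#'   (log-space bias).
#' @param split_fracs Chronological train/validation/test fractions.
#' @return A validated `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         epochs = 100L, embedding_dim = 128L, n_heads = 8L,
                         n_layers = 2L, ffn_dims = c(256L, 128L),
                         dropout = 0.1, alpha = 1, beta = 1, seed = 1L,
                         ablation = c("full", "transformer", "jth", "sta"),
                         window = 5L,
                         aggregate = c("mean", "last"),
                         attn_scale = c("per_head", "full"),
                         use_layernorm = TRUE, use_ffn = TRUE,
                         sta_heads = NULL, sta_layers = NULL,
                         lambda_t = NULL, learnable_constraint = TRUE,
                         constraint_mode = c("multiplicative", "additive"),
                         split_fracs = c(0.7, 0.15, 0.15)) {
  ablation <- match.arg(ablation)
  aggregate <- match.arg(aggregate)
  attn_scale <- match.arg(attn_scale)
  constraint_mode <- match.arg(constraint_mode)
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("invalid configuration: need alpha >= 0, beta >= 0, alpha + beta > 0",
         call. = FALSE)
  }
  if (is.null(sta_heads)) sta_heads <- n_heads
  if (is.null(sta_layers)) sta_layers <- n_layers
  if (embedding_dim %% n_heads != 0L || embedding_dim %% sta_heads != 0L) {
    stop("invalid configuration: embedding_dim must be divisible by the head counts",
         call. = FALSE)
  }
  if (length(ffn_dims) != 2L || any(ffn_dims < 1)) {
    stop("invalid configuration: ffn_dims must be two positive sizes",
         call. = FALSE)
  }
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), embedding_dim = as.integer(embedding_dim),
    n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
    ffn_dims = as.integer(ffn_dims), dropout = dropout,
    alpha = alpha, beta = beta, seed = as.integer(seed),
    ablation = ablation, window = as.integer(window), aggregate = aggregate,
    attn_scale = attn_scale, use_layernorm = isTRUE(use_layernorm),
    use_ffn = isTRUE(use_ffn), sta_heads = as.integer(sta_heads),
    sta_layers = as.integer(sta_layers), lambda_t = lambda_t,
    learnable_constraint = isTRUE(learnable_constraint),
    constraint_mode = constraint_mode, split_fracs = split_fracs
  ), class = "train_config")
}

#' Weighted dual-branch MSE objective
#'
#' `L = alpha * mean((y - y_pred)^2) + beta * mean((y - y_out)^2)`.
#'
#' @param y_true,y_pred_branch,y_out_branch Equal-length numeric vectors.
#' @param alpha,beta Non-negative branch weights.
#' @return Scalar loss.
#' @export
dual_branch_loss <- function(y_true, y_pred_branch, y_out_branch,
                             alpha = 1, beta = 1) {
  n <- length(y_true)
  if (length(y_pred_branch) != n || length(y_out_branch) != n || n < 1L) {
    stop("shape error: branch predictions must match y_true in length",
         call. = FALSE)
  }
  alpha * mean((y_true - y_pred_branch)^2) +
    beta * mean((y_true - y_out_branch)^2)
}

stf_adam_step <- function(p, n, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                          eps = 1e-8) {
  if (!is.list(p)) {
    g <- n$grad
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    upd <- lr * (m2 / (1 - b1^t)) / (sqrt(v2 / (1 - b2^t)) + eps)
    list(p = p - upd, m = m2, v = v2)
  } else {
    for (nm in names(p)) {
      r <- stf_adam_step(p[[nm]], n[[nm]], m[[nm]], v[[nm]], t, lr, b1, b2,
                         eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
}

stf_batch_loss_node <- function(preds, ys, alpha, beta) {
  nb <- length(ys)
  yc <- ad_const(matrix(ys, ncol = 1L))
  avg <- ad_const(matrix(1 / nb, 1L, nb))
  mse <- function(node) {
    d <- ad_sub(node, yc)
    ad_matmul(avg, ad_mul(d, d))
  }
  lj <- if (!is.null(preds$jth)) mse(preds$jth) else NULL
  ls <- if (!is.null(preds$sta)) mse(preds$sta) else NULL
  total <- if (!is.null(lj) && !is.null(ls)) {
    ad_add(ad_scale(lj, alpha), ad_scale(ls, beta))
  } else if (!is.null(lj)) lj else ls
  list(total = total,
       jth = if (!is.null(lj)) lj$val[1L] else NA_real_,
       sta = if (!is.null(ls)) ls$val[1L] else NA_real_)
}

#' Train the dual-branch model with Adam
#'
#' Optimizes the [dual_branch_loss()] objective over seeded minibatches.
#' When the STA branch is active and no constraint is supplied, the
#' feature-association matrix is built from the absolute Pearson
#' correlations of the training windows' feature rows (training data
#' only). Two calls with the same data and config produce identical
#' traces and parameters.
#'
#' @param data A `supervised_set` of training samples (chronological
#'   split already applied).
#' @param config A [train_config()].
#' @param validation Optional `supervised_set`; per-epoch validation MSE
#'   is recorded in the trace (diagnostics only, no early stopping).
#' @param constraint Optional precomputed
#'   [spatial_constraint_from_correlation()] object.
#' @return List with `model` (a `dual_branch_model`) and `trace`
#'   (data frame of per-epoch total and per-branch losses, validation
#'   MSE, and wall-clock seconds).
#' @export
train_model <- function(data, config, validation = NULL, constraint = NULL) {
  stopifnot(inherits(config, "train_config"))
  samples <- unclass(data)
  attributes(samples) <- NULL
  if (length(samples) < 1L) stop("need at least one training sample",
                                 call. = FALSE)
  n_features <- ncol(samples[[1]]$X)
  window <- nrow(samples[[1]]$X)

  if ("sta" %in% stf_active_branches(config$ablation) && is.null(constraint)) {
    rows <- do.call(rbind, lapply(samples, function(s) s$X))
    constraint <- spatial_constraint_from_correlation(
      rows, learnable = config$learnable_constraint)
  }
  model <- init_dual_branch_model(config, n_features, window,
                                  constraint = constraint)

  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      loss_jth = numeric(0), loss_sta = numeric(0),
                      val_mse = numeric(0), seconds = numeric(0))
  if (config$epochs < 1L) return(list(model = model, trace = trace))

  guard <- stf_local_seed(config$seed + 1L)
  on.exit(guard$restore())
  adam_m <- stf_map_nested(model$params, function(x) x * 0)
  adam_v <- adam_m
  step <- 0L
  n <- length(samples)
  last_finite <- 0L
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    order_idx <- sample.int(n)
    batch_starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_j <- 0; ep_s <- 0; ep_n <- 0
    for (b in batch_starts) {
      idx <- order_idx[b:min(b + config$batch_size - 1L, n)]
      ad_tape_start()
      Pn <- stf_wrap_nested(model$params)
      preds <- stf_forward_batch(Pn, samples[idx], model, training = TRUE)
      ys <- vapply(samples[idx], function(s) s$y, numeric(1))
      loss <- stf_batch_loss_node(preds, ys, config$alpha, config$beta)
      lv <- loss$total$val[1L]
      if (!is.finite(lv)) {
        ad_tape_stop()
        stop(sprintf(
          "divergence: non-finite loss at epoch %d (last finite epoch: %d)",
          epoch, last_finite), call. = FALSE)
      }
      ad_backward(loss$total)
      ad_tape_stop()
      step <- step + 1L
      upd <- stf_adam_step(model$params, Pn, adam_m, adam_v, step,
                           config$learning_rate)
      model$params <- upd$p; adam_m <- upd$m; adam_v <- upd$v
      nb <- length(idx)
      ep_loss <- ep_loss + lv * nb
      ep_j <- ep_j + ifelse(is.na(loss$jth), 0, loss$jth * nb)
      ep_s <- ep_s + ifelse(is.na(loss$sta), 0, loss$sta * nb)
      ep_n <- ep_n + nb
    }
    last_finite <- epoch
    val_mse <- NA_real_
    if (!is.null(validation) && length(validation) > 0L) {
      pv <- predict.dual_branch_model(model, validation)
      val_mse <- mean((pv$y_true - pv$y_hat)^2)
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, loss = ep_loss / ep_n,
      loss_jth = if ("jth" %in% model$active) ep_j / ep_n else NA_real_,
      loss_sta = if ("sta" %in% model$active) ep_s / ep_n else NA_real_,
      val_mse = val_mse,
      seconds = proc.time()[["elapsed"]] - t0))
  }
  list(model = model, trace = trace)
}
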