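# The dual-branch model: a temporal branch (JTH) and a spatiotemporally
# constrained branch (STA) trained jointly against the same next-step
# target, with inference as the arithmetic mean of the branch outputs.
# Ablation arms reduce the model to a plain Transformer encoder, the JTH
# branch alone, or the STA branch alone.

stf_map_nested <- function(p, f) {
  if (!is.list(p)) f(p) else lapply(p, stf_map_nested, f = f)
}

stf_wrap_nested <- function(p) {
  if (!is.list(p)) ad_leaf(p) else lapply(p, stf_wrap_nested)
}

stf_active_branches <- function(ablation) {
  switch(ablation,
         transformer = "jth",
         jth = "jth",
         sta = "sta",
         full = c("jth", "sta"),
         stop(sprintf("unknown ablation arm '%s'", ablation), call. = FALSE))
}

stf_uniform_constraint <- function(S, learnable) {
  A <- matrix(1, S, S)
  out <- list(A_raw = A, phi = A / S, sign = A * 0, learnable = isTRUE(learnable))
  if (out$learnable) out$A_free <- log(expm1(A))
  structure(out, class = "spatial_constraint")
}

#' Initialize a dual-branch model
#'
#' Draws all parameters (Glorot-uniform weights, zero biases, unit
#' layer-norm gains) under `config$seed`. The sinusoidal positional
#' encoding is shared by both branches; all learned parameters are
#' branch-specific. The ablation arm decides which branches exist:
#' `"transformer"` is a plain encoder over the scalar prevalence series
#' with last-step pooling, `"jth"` embeds the full feature rows with mean
#' aggregation, `"sta"` is the constrained-attention branch alone, and
#' `"full"` trains both.
#'
#' @param config A [train_config()].
#' @param n_features Number of engineered features F (also the number of
#'   "spatial" positions of the STA branch).
#' @param window Input window length T.
#' @param constraint Optional [spatial_constraint_from_correlation()]
#'   result; defaults to a uniform association matrix.
#' @return A `dual_branch_model` list.
#' @export
init_dual_branch_model <- function(config, n_features, window,
                                   constraint = NULL) {
  stopifnot(inherits(config, "train_config"))
  guard <- stf_local_seed(config$seed)
  on.exit(guard$restore())

  d <- config$embedding_dim
  active <- stf_active_branches(config$ablation)
  params <- list()
  if ("jth" %in% active) {
    f_in <- if (config$ablation == "transformer") 1L else n_features
    params$jth <- list(
      Win = stf_glorot(f_in, d), bin = stf_zeros(d),
      layers = lapply(seq_len(config$n_layers), function(i)
        stf_init_layer(d, config$ffn_dims[1])),
      head = stf_init_head(d, config$ffn_dims[1], config$ffn_dims[2])
    )
  }
  if ("sta" %in% active) {
    if (is.null(constraint)) {
      constraint <- stf_uniform_constraint(n_features,
                                           config$learnable_constraint)
    }
    params$sta <- list(
      Wlift = stf_glorot(n_features, d),
      Blift = stf_zeros(n_features, d),
      layers = lapply(seq_len(config$sta_layers), function(i) {
        lp <- stf_init_layer(d, config$ffn_dims[1])
        lp[c("W1", "b1", "W2", "b2", "ln2g", "ln2b")] <- NULL
        lp
      }),
      eta = stf_zeros(n_features),
      head = stf_init_head(d, config$ffn_dims[1], config$ffn_dims[2])
    )
    if (constraint$learnable) params$sta$Afree <- constraint$A_free
  }
  model <- structure(list(
    config = config, params = params, constraint = constraint,
    n_features = n_features, window = window, active = active,
    feature_names = NULL, scaler = NULL
  ), class = "dual_branch_model")
  model$n_params <- sum(unlist(stf_map_nested(params, length)))
  model
}

# forward a list of samples through the active branches as one stacked
# minibatch; Pn are wrapped parameter nodes. Returns B x 1 prediction
# nodes per branch.
stf_forward_batch <- function(Pn, samples, model, training) {
  cfg <- model$config
  B <- length(samples)
  T_len <- model$window
  out <- list(jth = NULL, sta = NULL)
  if ("jth" %in% model$active) {
    x_stack <- if (cfg$ablation == "transformer") {
      matrix(unlist(lapply(samples, function(s) s$y_hist)), ncol = 1L)
    } else {
      do.call(rbind, lapply(samples, function(s) s$X))
    }
    jcfg <- list(n_heads = cfg$n_heads, dropout = cfg$dropout,
                 attn_scale = cfg$attn_scale,
                 use_layernorm = cfg$use_layernorm, use_ffn = cfg$use_ffn,
                 aggregate = if (cfg$ablation == "transformer") "last"
                             else cfg$aggregate)
    out$jth <- stf_jth_branch_batch(x_stack, Pn$jth, jcfg, B, T_len, training)
  }
  if ("sta" %in% model$active) {
    x_stack <- do.call(rbind, lapply(samples, function(s) s$X))
    scfg <- list(sta_heads = cfg$sta_heads, dropout = cfg$dropout,
                 attn_scale = cfg$attn_scale,
                 use_layernorm = cfg$use_layernorm,
                 lambda_t = cfg$lambda_t,
                 constraint_mode = cfg$constraint_mode)
    out$sta <- stf_sta_branch_batch(x_stack, Pn$sta, scfg, model$constraint,
                                    B, T_len, training)
  }
  out
}

# chunked no-gradient forward over many samples; returns per-branch
# prediction vectors in scaled units
stf_predict_batch <- function(model, samples, chunk = 64L) {
  B <- length(samples)
  Pn <- stf_wrap_nested(model$params)
  yj <- rep(NA_real_, B); ys <- rep(NA_real_, B)
  at <- 1L
  while (at <= B) {
    idx <- at:min(at + chunk - 1L, B)
    preds <- stf_forward_batch(Pn, samples[idx], model, training = FALSE)
    if (!is.null(preds$jth)) yj[idx] <- preds$jth$val[, 1L]
    if (!is.null(preds$sta)) ys[idx] <- preds$sta$val[, 1L]
    at <- at + chunk
  }
  ens <- rowMeans(cbind(yj, ys), na.rm = TRUE)
  list(y_hat = ens, y_pred_branch = yj, y_out_branch = ys)
}

#' Dual-branch ensemble prediction for one input window
#'
#' Runs the active branches on a single window and returns their
#' arithmetic mean, `(y_pred + y_out) / 2`; a single-branch ablation
#' returns that branch's value unchanged. When the model carries a
#' recorded target scaler, outputs are mapped back to original percent
#' units.
#'
#' @param model A trained (or initialized) `dual_branch_model`.
#' @param window `T x F` feature window, or a supervised sample (list
#'   with `X` and, for the `"transformer"` arm, `y_hist`).
#' @return List with `y_hat` (ensemble), `y_pred_branch`, `y_out_branch`
#'   (NA for inactive branches).
#' @export
predict_ensemble <- function(model, window) {
  stopifnot(inherits(model, "dual_branch_model"))
  sample <- if (is.list(window) && !is.null(window$X)) window
            else list(X = as.matrix(window), y_hist = NULL)
  if (!is.null(sample$X) && (nrow(sample$X) != model$window ||
                             ncol(sample$X) != model$n_features)) {
    stop(sprintf("shape error: window must be %d x %d, got %d x %d",
                 model$window, model$n_features,
                 nrow(sample$X), ncol(sample$X)), call. = FALSE)
  }
  if (model$config$ablation == "transformer" && is.null(sample$y_hist)) {
    stop("the 'transformer' arm needs the scalar history `y_hist`",
         call. = FALSE)
  }
  p <- stf_predict_batch(model, list(sample))
  yj <- p$y_pred_branch[1L]; ys <- p$y_out_branch[1L]; yh <- p$y_hat[1L]
  if (!is.null(model$scaler)) {
    inv <- function(v) unname(inverse_zscore(v, model$scaler, "y"))
    yh <- inv(yh)
    if (!is.na(yj)) yj <- inv(yj)
    if (!is.na(ys)) ys <- inv(ys)
  }
  list(y_hat = unname(yh), y_pred_branch = unname(yj),
       y_out_branch = unname(ys))
}

#' Predict a set of supervised samples
#'
#' @param object A `dual_branch_model`.
#' @param samples A `supervised_set` (or list of samples).
#' @param ... Unused.
#' @return Data frame with true and predicted values (original units when
#'   the model carries a scaler) plus sample metadata.
#' @export
predict.dual_branch_model <- function(object, samples, ...) {
  samples <- unclass(samples)
  attributes(samples) <- NULL
  p <- stf_predict_batch(object, samples)
  grab <- function(field, default) {
    vapply(samples, function(s) {
      v <- s[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  y_true <- grab("y", NA_real_)
  out <- data.frame(state = grab("state", NA_character_),
                    stratum = grab("stratum", NA_character_),
                    time = grab("time", NA_real_),
                    y_true = y_true, y_hat = p$y_hat,
                    y_pred_branch = p$y_pred_branch,
                    y_out_branch = p$y_out_branch,
                    stringsAsFactors = FALSE)
  if (!is.null(object$scaler)) {
    for (col in c("y_true", "y_hat", "y_pred_branch", "y_out_branch")) {
      out[[col]] <- unname(inverse_zscore(out[[col]], object$scaler, "y"))
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds a hash of the training configuration so a reload
#' against a different configuration is detected.
#'
#' @param model A `dual_branch_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dual_branch_model"))
  payload <- list(model = model,
                  config_hash = stf_config_hash(model$config))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$config_hash, stf_config_hash(payload$model$config))) {
    stop("checkpoint config hash mismatch", call. = FALSE)
  }
  payload$model
}

stf_config_hash <- function(config) {
  digest_input <- paste(utils::capture.output(utils::str(config)),
                        collapse = "\n")
  as.character(sum(utf8ToInt(digest_input) * seq_len(nchar(digest_input,
                                                           type = "bytes"))))
}
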