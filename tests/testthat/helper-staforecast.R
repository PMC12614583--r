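# Shared fixtures. Heavy artifacts (the synthetic study panels and the
# trained ablation fits) are computed once per test run and memoized, so
# several test files can assert against the same runs.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# a tiny complete panel with a known linear trend (no noise)
trend_panel <- function(years = c(2000, 2019), trend = 0.5, base = 30,
                        n_strata = 1L, seed = 7L) {
  cfg <- synthetic_config(n_states = 1, years = years, n_strata = n_strata,
                          base_level = base, trend_per_year = trend,
                          ar_coefficient = 0, noise_sd = 0,
                          missing_rate = 0, outlier_rate = 0, seed = seed)
  generate_state_panel(cfg, 1)
}

# small branch parameter sets with hand-controllable weights
toy_jth_params <- function(f_in, d, seed = 1L) {
  set.seed(seed)
  list(Win = matrix(stats::rnorm(f_in * d, sd = 0.3), f_in, d),
       bin = matrix(0, 1, d),
       layers = list(list(Wq = diag(d), Wk = diag(d), Wv = diag(d),
                          Wo = diag(d))),
       head = list(W1 = matrix(stats::rnorm(d * 4, sd = 0.3), d, 4),
                   b1 = matrix(0, 1, 4),
                   W2 = matrix(stats::rnorm(4 * 3, sd = 0.3), 4, 3),
                   b2 = matrix(0, 1, 3),
                   Wo = matrix(stats::rnorm(3), 3, 1),
                   bo = matrix(0, 1, 1)))
}

# the study conditions used by the acceptance-style experiments:
# 10 states, 40 years, AR(1) + trend with noise_sd = 0.5 (generator
# defaults), complete panels
accept_prep <- function() {
  fixture("accept_prep", function() {
    cfg <- synthetic_config(seed = 1L)
    panels <- generate_panels(cfg, degrade = FALSE)
    pcfg <- pipeline_config(window = 5L)
    lapply(panels, staforecast:::stf_prepare_state, cfg = pcfg)
  })
}

accept_train_set <- function() {
  fixture("accept_train", function() {
    prep <- accept_prep()
    structure(do.call(c, lapply(prep, function(p) unclass(p$splits$train))),
              class = "supervised_set")
  })
}

# desk-scale model configuration for the synthetic experiments (the
# methods vignette documents these choices)
accept_config <- function(arm, seed) {
  train_config(embedding_dim = 16L, n_heads = 2L, n_layers = 1L,
               sta_layers = 1L, sta_heads = 2L, ffn_dims = c(32L, 16L),
               dropout = 0, epochs = 100L, batch_size = 32L, seed = seed,
               window = 5L, learning_rate = 0.01, ablation = arm,
               use_layernorm = FALSE)
}

accept_fit <- function(arm, seed) {
  fixture(sprintf("fit_%s_%d", arm, seed), function() {
    train_model(accept_train_set(), accept_config(arm, seed))
  })
}

# per-state metrics of a fitted model on the held-out test samples
accept_eval <- function(fit) {
  prep <- accept_prep()
  per_state <- lapply(names(prep), function(st) {
    ev <- staforecast:::stf_eval_samples(fit$model, prep[[st]]$splits$test,
                                         prep[[st]]$scaler)
    list(state = st, metrics = ev$metrics, pred = ev$pred)
  })
  pooled <- do.call(rbind, lapply(per_state, function(x) x$pred))
  list(per_state = per_state,
       pooled = compute_metrics(pooled$y_true, pooled$y_hat))
}

accept_state_mean <- function(ev, metric) {
  mean(vapply(ev$per_state, function(x) x$metrics[[metric]], numeric(1)))
}
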