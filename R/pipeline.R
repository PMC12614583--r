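# End-to-end experiment runner: simulate (or read) panels, clean them,
# engineer features, train the requested ablation arms over the requested
# seeds, evaluate with the five-metric protocol, run paired significance
# tests between arms, attribute the final model's predictions, and leave
# a manifest sufficient to reproduce the run bit-for-bit on one machine.

#' Default pipeline configuration
#'
#' A nested list understood by [run_pipeline()]; any subset can be
#' overridden. `synthetic` holds [synthetic_config()] arguments (ignored
#' when `data_files` supplies CSV paths); `model` holds [train_config()]
#' arguments shared by all arms; `ablations` and `seeds` define the
#' experiment grid. `pool_states = FALSE` trains one model per state
#' (state-specific independent modeling); `TRUE` trains a single model on
#' all states' samples.
#'
#' @param ... Named overrides merged over the defaults (one level deep
#'   for nested lists). `degrade = FALSE` skips the missingness/outlier
#'   degradation of simulated panels.
#' @return Pipeline configuration list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    synthetic = list(),
    degrade = TRUE,
    data_files = NULL,
    seeds = c(1L, 2L, 3L),
    ablations = "full",
    model = list(),
    window = 5L,
    features = list(),
    split_fracs = c(0.7, 0.15, 0.15),
    pool_states = FALSE,
    explain = list(enabled = TRUE, n_permutations = 32L, n_samples = 8L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      for (k in names(over[[nm]])) base[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

stf_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

# clean one panel and build scaled supervised splits; all statistics
# (imputation, fences, scalers) come from the training period only
stf_prepare_state <- function(panel, cfg) {
  years <- sort(unique(panel$year))
  cutoff <- years[max(1L, floor(cfg$split_fracs[1] * length(years)))]
  fit_idx <- which(panel$year <= cutoff)
  clean <- preprocess_panel(panel, fit_idx = fit_idx,
                            outlier_fit_idx = seq_len(nrow(panel)))
  spec <- do.call(feature_spec, cfg$features)
  fm <- build_features(clean$panel, spec)
  fm <- zscore_normalize(fm, fit_idx = which(fm$valid_mask &
                                               fm$times <= cutoff))
  samples <- assemble_supervised(fm, window = cfg$window)
  splits <- split_supervised(samples, fracs = cfg$split_fracs)
  list(splits = splits, scaler = fm$scaler, feature_names = fm$feature_names,
       report = clean$report, cutoff_year = cutoff)
}

# predictions are never scored against imputed targets: a cell filled by
# mean imputation is not an observation
stf_eval_samples <- function(model, samples, scaler) {
  model$scaler <- scaler
  observed <- !vapply(samples, function(s) isTRUE(s$y_imputed), logical(1))
  if (sum(observed) >= 2L) samples <- samples[observed]
  pred <- predict.dual_branch_model(model, samples)
  list(pred = pred, metrics = compute_metrics(pred$y_true, pred$y_hat))
}

#' Run the full experiment pipeline
#'
#' Executes simulate/load -> preprocess -> features -> train (per
#' ablation arm, per seed) -> evaluate -> explain, and writes
#' `metrics.json`, `metrics_long.csv`, `significance.csv`,
#' `importance.csv` / `shap_values.csv` / `dependence.csv`, and
#' `manifest.json` into `out_dir`.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file of
#'   the same shape.
#' @param out_dir Output run directory (created if needed).
#' @return Invisibly, a list with the metrics tables, significance
#'   reports, attribution report, manifest, and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timing <- list()
  stamp <- function(stage, t0) {
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  t0 <- proc.time()[["elapsed"]]
  input_hashes <- NULL
  if (length(config$data_files) > 0L) {
    panels <- lapply(config$data_files, read_panel_csv)
    names(panels) <- vapply(panels, function(p) attr(p, "state_code"),
                            character(1))
    input_hashes <- as.list(tools::md5sum(unlist(config$data_files)))
  } else {
    syn_cfg <- do.call(synthetic_config, config$synthetic)
    panels <- generate_panels(syn_cfg, degrade = isTRUE(config$degrade))
  }
  stamp("simulate_or_load", t0)

  t0 <- proc.time()[["elapsed"]]
  prep <- lapply(panels, stf_prepare_state, cfg = config)
  stamp("preprocess_features", t0)

  t0 <- proc.time()[["elapsed"]]
  states <- names(prep)
  long <- data.frame()
  models <- list()
  for (arm in config$ablations) {
    for (seed in config$seeds) {
      marg <- config$model
      marg$seed <- seed
      marg$ablation <- arm
      marg$window <- config$window
      tc <- do.call(train_config, marg)
      if (isTRUE(config$pool_states)) {
        train_all <- do.call(c, lapply(prep, function(p)
          unclass(p$splits$train)))
        val_all <- do.call(c, lapply(prep, function(p)
          unclass(p$splits$validation)))
        fit <- train_model(structure(train_all, class = "supervised_set"),
                           tc, validation = val_all)
        for (st in states) {
          ev <- stf_eval_samples(fit$model, prep[[st]]$splits$test,
                                 prep[[st]]$scaler)
          long <- rbind(long, data.frame(
            state = st, ablation = arm, seed = seed,
            mae = ev$metrics$mae, rmse = ev$metrics$rmse,
            smape = ev$metrics$smape, r2 = ev$metrics$r2,
            mase = ev$metrics$mase, n = ev$metrics$n))
        }
        fit$model$feature_names <- prep[[1]]$feature_names
        models[[paste(arm, seed, sep = "_")]] <- fit$model
      } else {
        for (st in states) {
          fit <- train_model(prep[[st]]$splits$train, tc,
                             validation = prep[[st]]$splits$validation)
          ev <- stf_eval_samples(fit$model, prep[[st]]$splits$test,
                                 prep[[st]]$scaler)
          long <- rbind(long, data.frame(
            state = st, ablation = arm, seed = seed,
            mae = ev$metrics$mae, rmse = ev$metrics$rmse,
            smape = ev$metrics$smape, r2 = ev$metrics$r2,
            mase = ev$metrics$mase, n = ev$metrics$n))
          fit$model$feature_names <- prep[[st]]$feature_names
          models[[paste(arm, seed, st, sep = "_")]] <- fit$model
        }
      }
    }
  }
  stamp("train_evaluate", t0)

  # per-arm aggregation: state-mean per seed, then mean +/- sd over seeds
  metric_names <- c("mae", "rmse", "smape", "r2", "mase")
  summary_tbl <- list()
  for (arm in config$ablations) {
    arm_rows <- long[long$ablation == arm, ]
    per_seed <- lapply(split(arm_rows, arm_rows$seed), function(df) {
      r <- as.list(colMeans(df[metric_names]))
      r$n <- sum(df$n)
      structure(r, class = "metrics_report")
    })
    summary_tbl[[arm]] <- aggregate_runs(per_seed)
  }

  # paired significance across states: reference arm vs the others
  signif_tbl <- data.frame()
  if (length(config$ablations) > 1L && length(states) > 1L) {
    ref <- config$ablations[length(config$ablations)]
    per_state <- function(arm, metric) {
      df <- long[long$ablation == arm, ]
      vapply(split(df[[metric]], df$state), mean, numeric(1))[states]
    }
    for (arm in setdiff(config$ablations, ref)) {
      for (metric in metric_names) {
        res <- tryCatch(paired_ttest(per_state(ref, metric),
                                     per_state(arm, metric)),
                        error = function(e) NULL)
        if (!is.null(res)) {
          signif_tbl <- rbind(signif_tbl, data.frame(
            reference = ref, baseline = arm, metric = metric,
            t = res$t, p_value = res$p_value, df = res$df))
        }
      }
    }
  }

  t0 <- proc.time()[["elapsed"]]
  attribution <- NULL
  if (isTRUE(config$explain$enabled)) {
    key <- grep(paste0("^", config$ablations[length(config$ablations)], "_"),
                names(models), value = TRUE)[1]
    expl_model <- models[[key]]
    st1 <- states[1]
    expl_model$scaler <- prep[[st1]]$scaler
    n_s <- min(config$explain$n_samples, length(prep[[st1]]$splits$test))
    attribution <- explain_model(
      expl_model, prep[[st1]]$splits$test[seq_len(n_s)],
      background_samples = prep[[st1]]$splits$train,
      n_permutations = config$explain$n_permutations,
      seed = config$seeds[1])
  }
  stamp("explain", t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("staforecast")),
    created = stf_now(),
    config = config,
    seeds = config$seeds,
    input_hashes = input_hashes,
    timing_seconds = timing,
    r_version = R.version.string
  )

  write_json_file <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  metrics_out <- lapply(summary_tbl, function(r) {
    list(mean = as.list(r$mean_sd["mean", ]), sd = as.list(r$mean_sd["sd", ]),
         n = r$n)
  })
  write_json_file(metrics_out, "metrics.json")
  utils::write.csv(long, file.path(out_dir, "metrics_long.csv"),
                   row.names = FALSE)
  if (nrow(signif_tbl) > 0L) {
    utils::write.csv(signif_tbl, file.path(out_dir, "significance.csv"),
                     row.names = FALSE)
  }
  if (!is.null(attribution)) {
    utils::write.csv(attribution$importance,
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(attribution$shap_values),
                     file.path(out_dir, "shap_values.csv"), row.names = FALSE)
    utils::write.csv(attribution$dependence,
                     file.path(out_dir, "dependence.csv"), row.names = FALSE)
  }
  write_json_file(manifest, "manifest.json")

  invisible(list(summary = summary_tbl, long = long,
                 significance = signif_tbl, attribution = attribution,
                 manifest = manifest, models = models, out_dir = out_dir))
}
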