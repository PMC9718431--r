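# End-to-end pipeline: simulate -> label -> features -> scale -> split ->
# train/evaluate -> cross-validate -> stats, with checksummed artifacts and
# a manifest, all driven by one global seed.

#' Pipeline configuration
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param out_dir output directory for artifacts.
#' @param sim a [sim_config()] (its `seed` is overridden by `seed`).
#' @param criteria an [ad_criteria()].
#' @param train a [train_config()] for the binary task (its `seed` is
#'   overridden by `seed`).
#' @param n_windows target number of feature windows (data points).
#' @param scaling `"same-day"` or `"train-only"` min-max scaling.
#' @param alpha significance level for the statistical battery.
#' @param quiet suppress per-stage progress messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("adreflex_"),
                            sim = sim_config(), criteria = ad_criteria(),
                            train = train_config(), n_windows = 2200L,
                            scaling = c("same-day", "train-only"),
                            alpha = 0.01, quiet = FALSE) {
  sim$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 criteria = criteria, train = train,
                 n_windows = as.integer(n_windows),
                 scaling = match.arg(scaling), alpha = alpha,
                 quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[adreflex] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> label -> features -> scale -> split -> train ->
#' evaluate -> cross-validate -> stats, writes each stage's artifact under
#' `out_dir`, and finishes with `manifest.json` listing every artifact with
#' its MD5 checksum. Identical configurations produce byte-identical
#' artifacts and manifests.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    ts <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stage_msg(config$quiet, "%-10s %6.1f s", name, proc.time()[3] - ts)
    res
  }

  cohort <- stage("simulate", simulate_cohort(config$sim))

  labels_df <- stage("label",
                     label_cohort(cohort, config$sim, config$criteria))
  rate <- cohort_ad_rate(labels_df)
  write.csv(labels_df, file.path(config$out_dir, "labels.csv"),
            row.names = FALSE)

  windows <- stage("features", {
    w <- cohort_windows(cohort, config$sim, config$criteria)
    sample_windows(w, config$n_windows, seed = config$seed)
  })

  sp <- split_stratified(windows$label, config$train)
  fm <- feature_matrix(windows, scaling = config$scaling,
                       train_idx = sp$train)
  write.csv(fm$windows, file.path(config$out_dir, "features.csv"),
            row.names = FALSE)

  binary <- stage("train", {
    y_bin <- ifelse(windows$label == "ad", "ad", "non_ad")
    model <- train_model(fm$x[sp$train, ], y_bin[sp$train], config$train,
                         x_val = fm$x[sp$val, ], y_val = y_bin[sp$val])
    report <- evaluate(model, fm$x[sp$test, ], y_bin[sp$test])
    save_model(model, file.path(config$out_dir, "model_binary.json"))
    list(model = model, report = report)
  })
  write_json_file(list(
    accuracy = binary$report$accuracy,
    sensitivity = binary$report$sensitivity,
    specificity = binary$report$specificity,
    f1 = binary$report$f1, auc_roc = binary$report$auc_roc,
    n_test = binary$report$n,
    split_sizes = lapply(sp, length),
    confusion = as.data.frame(as.table(binary$report$confusion))
  ), file.path(config$out_dir, "eval_binary.json"))

  cv <- stage("crossval", {
    mc_cfg <- config$train
    mc_cfg$task <- "multiclass"
    mc_cfg$cv_folds <- min(config$train$cv_folds,
                           min(table(windows$label)))
    if (mc_cfg$cv_folds >= 2L)
      cross_validate(fm$x, windows$label, mc_cfg) else NULL
  })
  if (!is.null(cv)) {
    write_json_file(list(
      cv_mean = cv$cv_mean, cv_sd = cv$cv_sd,
      fold_accuracy = cv$fold_accuracy,
      per_class_recall = as.list(cv$per_class_recall),
      confusion = as.data.frame(as.table(cv$confusion))
    ), file.path(config$out_dir, "cv_multiclass.json"))
  }

  stats_df <- stage("stats", {
    rbind(compare_ad_vs_non(windows, alpha = config$alpha),
          compare_stimuli(windows, alpha = config$alpha))
  })
  write.csv(stats_df, file.path(config$out_dir, "stats.csv"),
            row.names = FALSE)

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config$sim),
    n_windows = nrow(windows),
    ad_rate = rate$rate,
    artifacts = lapply(files, function(f) {
      p <- file.path(config$out_dir, f)
      list(file = f, md5 = unname(tools::md5sum(p)),
           bytes = file.size(p))
    })
  )
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  stage_msg(config$quiet, "done       %6.1f s total", proc.time()[3] - t0)
  invisible(list(windows = windows, labels = labels_df, ad_rate = rate,
                 split = sp, binary = binary$report, model = binary$model,
                 cv = cv, stats = stats_df, manifest = manifest,
                 scaling_state = fm$state))
}
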