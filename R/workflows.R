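# End-to-end workflows: preprocessing pipelines, supervised runs and
# transfer runs, with YAML configuration and reproducible artifact
# directories.

#' Preprocess a raw multi-omics dataset
#'
#' Applies the standard pipeline per omics: log2(x + 1) for expression
#' modalities (any omics whose name is not `"methylation"` by default),
#' variance filtering with the modality defaults, then min-max scaling to
#' \[0, 1\]. Training statistics (kept feature ids, min/max) are returned
#' so held-out data can be transformed identically.
#'
#' @param dataset A [multiomics_dataset()] of raw blocks.
#' @param log2_omics Names of blocks receiving the log2 transform;
#'   defaults to every block except `"methylation"`.
#' @param thresholds Optional named variance thresholds overriding the
#'   modality defaults.
#' @param fit Optional `$stats` of a previous call, to apply training
#'   statistics to held-out data.
#' @return A list: `dataset` (preprocessed) and `stats` (per-omics kept
#'   features and min/max tibbles).
#' @export
preprocess_dataset <- function(dataset, log2_omics = NULL,
                               thresholds = NULL, fit = NULL) {
  if (is.null(log2_omics)) {
    log2_omics <- setdiff(names(dataset$blocks), "methylation")
  }
  stats_out <- list()
  blocks <- list()
  for (nm in names(dataset$blocks)) {
    b <- dataset$blocks[[nm]]
    do_log2 <- nm %in% log2_omics
    if (is.null(fit)) {
      if (do_log2) b$values <- log2(b$values + 1)
      thr <- if (!is.null(thresholds) && nm %in% names(thresholds)) {
        thresholds[[nm]]
      } else if (nm %in% names(default_variance_thresholds)) {
        NULL  # variance_filter applies the modality default
      } else {
        0
      }
      b <- variance_filter(b, thr)
      pp <- preprocess_omics(b, do_log2 = FALSE)
      blocks[[nm]] <- pp$block
      stats_out[[nm]] <- list(features = colnames(b$values),
                              minmax = pp$stats, log2 = do_log2)
    } else {
      st <- fit[[nm]]
      b$values <- b$values[, st$features, drop = FALSE]
      pp <- preprocess_omics(b, do_log2 = st$log2, fit_stats = st$minmax)
      blocks[[nm]] <- pp$block
      stats_out[[nm]] <- st
    }
  }
  list(dataset = multiomics_dataset(blocks, labels = dataset$labels,
                                    mask = dataset$mask),
       stats = stats_out)
}

# Recognized run-configuration keys and their defaults.
run_config_defaults <- function() {
  c(as.list(learner_config()),
    list(ways = 4, shots = 10, inner_rate = 0.01, outer_rate = 0.001,
         inner_steps = 1, n_sub = 4, n_outer = 50, kde_grid = 512,
         literal_sign = FALSE, finetune_epochs = 100, finetune_lr = 1e-3,
         test_fraction = 0.2, seed = 1, repeats = 1))
}

#' Load a run configuration from YAML
#'
#' Every field has a default; unknown keys are rejected before any
#' computation starts.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A named list of resolved settings.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}

split_run_config <- function(cfg) {
  lc <- do.call(learner_config, cfg[intersect(names(cfg),
                                              names(as.list(learner_config())))])
  mc <- do.call(meta_config, cfg[intersect(names(cfg),
                                           names(as.list(meta_config())))])
  list(learner = lc, meta = mc, cfg = cfg)
}

#' Supervised end-to-end run
#'
#' Stratified split, base-learner training, prediction and evaluation;
#' optionally repeated with distinct seeds to report mean and standard
#' deviation of the four metrics.
#'
#' @param data A [multiomics_dataset()] (already preprocessed) or a
#'   dataset directory readable by [read_dataset()].
#' @param config Resolved configuration list from [load_run_config()], a
#'   YAML path, or `NULL` for defaults.
#' @param out_dir Optional artifact directory; receives the resolved
#'   config, per-seed metrics, predictions and loss traces.
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param repeats Number of repeated runs.
#' @return A list: `metrics` (per-seed tibble), `summary` (mean/sd),
#'   `learner` (from the first seed) and `predictions`.
#' @export
run_supervised <- function(data, config = NULL, out_dir = NULL, seed = 1,
                           repeats = 1) {
  if (is.character(data)) data <- read_dataset(data)
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config)) config <- load_run_config()
  parts <- split_run_config(config)
  rows <- vector("list", repeats)
  first <- NULL
  for (r in seq_len(repeats)) {
    s <- seed + r - 1L
    sp <- stratified_split(data, parts$cfg$test_fraction, rng_seed = s)
    learner <- train_base_learner(sp$train, parts$learner, seed = s)
    preds <- predict_subtypes(learner, sp$test)
    rows[[r]] <- dplyr::mutate(evaluate_metrics(sp$test$labels, preds),
                               seed = s, .before = 1)
    if (r == 1L) first <- list(learner = learner, predictions = preds,
                               split = sp)
  }
  metrics <- dplyr::bind_rows(rows)
  summary <- metrics |>
    tidyr::pivot_longer(-"seed", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(parts$cfg, file.path(out_dir, "config.yaml"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(summary, file.path(out_dir, "metrics_summary.csv"))
    readr::write_csv(first$predictions, file.path(out_dir,
                                                  "predictions.csv"))
    readr::write_csv(first$learner$trace, file.path(out_dir,
                                                    "loss_trace.csv"))
  }
  list(metrics = metrics, summary = summary, learner = first$learner,
       predictions = first$predictions)
}

#' Transfer end-to-end run
#'
#' Meta-trains on the external cohort(s), fine-tunes on an N-way K-shot
#' target subset and evaluates on the remaining target samples. A scratch
#' baseline (same architecture trained only on the fine-tuning subset) is
#' computed alongside so the report exposes the transfer gain.
#'
#' @param external External dataset(s) (objects or directories).
#' @param target Target dataset (object or directory).
#' @param config Resolved configuration list, YAML path or `NULL`.
#' @param out_dir Optional artifact directory.
#' @param seed Integer seed.
#' @return A list: `report` (tibble with `meta` and `scratch` rows plus
#'   the accuracy gain) and the fitted `transfer` object.
#' @export
run_transfer <- function(external, target, config = NULL, out_dir = NULL,
                         seed = 1) {
  if (is.character(target)) target <- read_dataset(target)
  if (inherits(external, "multiomics_dataset")) external <- list(external)
  external <- lapply(external, function(e) {
    if (is.character(e)) read_dataset(e) else e
  })
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config)) config <- load_run_config()
  parts <- split_run_config(config)
  fit <- meta_train_and_finetune(external, target, parts$learner,
                                 parts$meta, seed = seed)
  # scratch baseline: identical architecture and budget, fine-tuning set
  # only, no meta-initialization
  scratch_cfg <- parts$learner
  scratch_cfg$epochs <- parts$meta$finetune_epochs
  scratch_cfg$lr <- parts$meta$finetune_lr
  ft_ids <- match(fit$finetune_ids, target$sample_ids)
  scratch <- train_base_learner(subset_dataset(target, ft_ids),
                                scratch_cfg, seed = seed)
  scratch_preds <- predict_subtypes(scratch, fit$eval_set)
  scratch_metrics <- evaluate_metrics(fit$eval_set$labels, scratch_preds)
  report <- dplyr::bind_rows(
    dplyr::mutate(fit$report, model = "meta", .before = 1),
    dplyr::mutate(scratch_metrics, model = "scratch", .before = 1)
  )
  report$accuracy_gain <- report$accuracy[report$model == "meta"] -
    report$accuracy[report$model == "scratch"]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(c(parts$cfg, seed = seed),
                     file.path(out_dir, "config.yaml"))
    readr::write_csv(report, file.path(out_dir, "transfer_report.csv"))
    jsonlite::write_json(
      list(report = report, finetune_ids = fit$finetune_ids),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(report = report, transfer = fit, scratch = scratch)
}
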