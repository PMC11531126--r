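# Benchmark harness: run the selector x predictor grid over datasets,
# collect metric reports, aggregate them, and count per-metric wins.
# Feature selection always happens inside each train split, never on the
# full data, so the test part stays untouched.

selector_registry <- function(configs) {
  list(
    proposed = function(train) hybrid_pipeline(train, configs)$selection,
    lasso = function(train) lasso_select(train, configs$lasso),
    rsf_vs = function(train) rsf_select(train, configs$rsf),
    scad = function(train) scad_select(train, configs$scad),
    coxboost = function(train) do.call(coxboost_select,
                                       c(list(data = train),
                                         configs$coxboost)))
}

#' Run one selector/predictor cell
#'
#' Splits the data (stratified on the event indicator), runs the selector on
#' the training part only, restricts both parts to the selected features,
#' fits the predictor on the training part and evaluates IPCW Brier,
#' C-index and IAE/ISE on the test part. An empty selection falls back to
#' the selector's top-1 ranked feature, flagged in the report.
#'
#' @param data A [survival_dataset()].
#' @param selector One of `"proposed"`, `"lasso"`, `"rsf_vs"`, `"scad"`,
#'   `"coxboost"`.
#' @param predictor `"coxph"` or `"rsf"`.
#' @param seed Integer seed for the split and all seeded components.
#' @param test_fraction Test fraction (default 0.3).
#' @param configs Per-selector configurations, as in [run_all_selectors()];
#'   built from `seed` when omitted.
#' @param rsf_predictor_B Tree count for the RSF predictor (default 300).
#' @return A one-row data frame: dataset, selector, predictor, seed, ibs,
#'   c_index, iae, ise, n_test, n_features, fallback.
#' @export
run_cell <- function(data, selector, predictor = c("coxph", "rsf"),
                     seed = 1L, test_fraction = 0.3, configs = NULL,
                     rsf_predictor_B = 300L) {
  predictor <- match.arg(predictor)
  if (is.null(configs)) configs <- default_selector_configs(seed = seed)
  runners <- selector_registry(configs)
  if (!selector %in% names(runners)) {
    stop("unknown selector '", selector, "'")
  }
  parts <- split_train_test(data, test_fraction, seed)
  fs <- runners[[selector]](parts$train)
  fallback <- FALSE
  feats <- fs$features
  if (length(feats) == 0L) {
    fallback <- TRUE
    if (is.null(fs$all_scores) || all(!is.finite(fs$all_scores))) {
      stop("empty selection and no fallback ranking available")
    }
    feats <- names(which.max(fs$all_scores))
    message("empty '", selector, "' selection: falling back to top-ranked ",
            "feature '", feats, "'")
  }
  train <- subset_dataset(parts$train, features = feats)
  test <- subset_dataset(parts$test, features = feats)
  eval_times <- sort(unique(test$times[test$events == 1]))
  report <- if (predictor == "coxph") {
    fit <- fit_cox(train)
    surv <- predict_survival(fit, test$covariates, eval_times)
    risk <- drop(test$covariates %*% fit$beta)
    metric_report(surv, test, risk = risk)
  } else {
    forest <- grow_forest(train, B = rsf_predictor_B, seed = seed)
    surv <- ensemble_chf(forest, test$covariates, eval_times)
    risk <- forest_mortality(attr(surv, "chf"))
    metric_report(surv, test, risk = risk)
  }
  data.frame(dataset = data$name, selector = selector, predictor = predictor,
             seed = seed, ibs = report$ibs, c_index = report$c_index,
             iae = report$iae, ise = report$ise, n_test = report$n_test,
             n_features = length(feats), fallback = fallback,
             stringsAsFactors = FALSE)
}

#' Run a benchmark grid
#'
#' Repeats [run_cell()] over datasets, selectors, predictors and seeds.
#' Failing cells are recorded as missing (with a warning) and the run
#' continues.
#'
#' @param datasets Named list of [survival_dataset()]s.
#' @param selectors,predictors Character vectors of selector and predictor
#'   labels.
#' @param n_repeats Number of repeated splits per cell (default 10).
#' @param base_seed Seed for repeat `r` is `base_seed + r - 1`.
#' @param ... Passed to [run_cell()].
#' @return A data frame of cell reports, one row per
#'   dataset/selector/predictor/repeat.
#' @export
run_benchmark <- function(datasets, selectors = c("proposed", "lasso",
                                                  "rsf_vs", "scad",
                                                  "coxboost"),
                          predictors = c("coxph", "rsf"), n_repeats = 10L,
                          base_seed = 1L, ...) {
  stopifnot(length(selectors) >= 1, length(predictors) >= 1, n_repeats >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, `[[`, character(1), "name")
  }
  if (anyDuplicated(names(datasets))) {
    stop("dataset labels must be unique")
  }
  rows <- list()
  for (ds in names(datasets)) {
    datasets[[ds]]$name <- ds  # reports are keyed by the list label
    for (sel in selectors) {
      for (pred in predictors) {
        for (r in seq_len(n_repeats)) {
          seed <- base_seed + r - 1L
          cell <- tryCatch(
            run_cell(datasets[[ds]], sel, pred, seed = seed, ...),
            error = function(e) {
              warning("cell (", ds, ", ", sel, ", ", pred, ", seed ", seed,
                      ") failed: ", conditionMessage(e))
              NULL
            })
          if (!is.null(cell)) rows[[length(rows) + 1L]] <- cell
        }
      }
    }
  }
  if (length(rows) == 0L) stop("every benchmark cell failed")
  do.call(rbind, rows)
}

#' Aggregate benchmark reports
#'
#' Averages metrics over repeats first, then over datasets: per predictor a
#' per-dataset table (rows = dataset x metric, columns = selectors) and a
#' grand table of per-selector means across datasets (the "Average" row of
#' a benchmark table).
#'
#' @param reports Data frame from [run_benchmark()].
#' @return A list with `per_dataset` (mean metrics per
#'   dataset/selector/predictor) and `average` (per selector/predictor,
#'   averaged over datasets), plus `n_missing_cells`.
#' @export
aggregate_reports <- function(reports) {
  metrics <- c("ibs", "c_index", "iae", "ise")
  key <- interaction(reports$dataset, reports$selector, reports$predictor,
                     drop = TRUE)
  per_ds <- do.call(rbind, lapply(split(reports, key), function(g) {
    out <- g[1, c("dataset", "selector", "predictor")]
    for (m in metrics) out[[m]] <- mean(g[[m]])
    out$n_repeats <- nrow(g)
    out
  }))
  rownames(per_ds) <- NULL
  key2 <- interaction(per_ds$selector, per_ds$predictor, drop = TRUE)
  avg <- do.call(rbind, lapply(split(per_ds, key2), function(g) {
    out <- g[1, c("selector", "predictor")]
    for (m in metrics) out[[m]] <- mean(g[[m]])
    out$n_datasets <- nrow(g)
    out
  }))
  rownames(avg) <- NULL
  full <- length(unique(reports$dataset)) *
    length(unique(reports$selector)) * length(unique(reports$predictor))
  list(per_dataset = per_ds, average = avg,
       n_missing_cells = full - nrow(per_ds))
}

#' Win counts per selector
#'
#' For every dataset, predictor and metric the best selector (minimum for
#' IBS/IAE/ISE, maximum for the C-index) receives one win; exact ties split
#' the win equally. Wins sum to datasets x metrics per predictor.
#'
#' @param reports Data frame from [run_benchmark()] (repeats are averaged
#'   first).
#' @param metrics Metrics to score (default IBS, C-index, IAE).
#' @return A data frame of win counts per selector and predictor.
#' @export
vote_tally_comparison <- function(reports,
                                  metrics = c("ibs", "c_index", "iae")) {
  per_ds <- aggregate_reports(reports)$per_dataset
  higher_better <- c(ibs = FALSE, c_index = TRUE, iae = FALSE, ise = FALSE)
  out <- list()
  for (pred in unique(per_ds$predictor)) {
    sub <- per_ds[per_ds$predictor == pred, , drop = FALSE]
    wins <- stats::setNames(numeric(length(unique(sub$selector))),
                            unique(sub$selector))
    for (ds in unique(sub$dataset)) {
      cell <- sub[sub$dataset == ds, , drop = FALSE]
      for (m in metrics) {
        v <- cell[[m]]
        best <- if (higher_better[[m]]) v == max(v) else v == min(v)
        wins[cell$selector[best]] <- wins[cell$selector[best]] +
          1 / sum(best)
      }
    }
    out[[pred]] <- data.frame(predictor = pred, selector = names(wins),
                              wins = as.numeric(wins),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
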