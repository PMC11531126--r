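#' Construct a survival dataset
#'
#' Bundles observed times, event indicators and a numeric covariate matrix
#' into a validated `survival_dataset` object, the common input of every
#' selector, predictor and metric in the package.
#'
#' @param times Numeric vector of observed times \eqn{Y_i = \min(T_i, C_i)};
#'   strictly positive and finite.
#' @param events Integer/numeric vector of censoring indicators
#'   \eqn{\delta_i \in \{0, 1\}} (1 = event observed). At least one event is
#'   required.
#' @param covariates Numeric matrix (or data frame) with one row per subject.
#' @param feature_names Optional character vector of unique column names;
#'   defaults to the matrix column names or `x1..xp`.
#' @param name Free-text label for the dataset.
#' @return An object of class `survival_dataset` with elements `times`,
#'   `events`, `covariates` (named matrix), `name`.
#' @export
survival_dataset <- function(times, events, covariates,
                             feature_names = NULL, name = "dataset") {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  times <- as.numeric(times)
  events <- as.numeric(events)
  n <- length(times)
  if (n < 2L) stop("need at least 2 subjects, got ", n)
  if (length(events) != n || nrow(covariates) != n) {
    stop("times (", n, "), events (", length(events), ") and covariate rows (",
         nrow(covariates), ") must agree")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all observed times must be strictly positive and finite")
  }
  if (!all(events %in% c(0, 1))) {
    stop("event indicators must be coded 0/1; found: ",
         paste(utils::head(setdiff(unique(events), c(0, 1))), collapse = ", "))
  }
  if (sum(events) < 1) stop("dataset contains no observed events")
  if (anyNA(covariates)) stop("covariates contain missing values")
  if (is.null(feature_names)) {
    feature_names <- colnames(covariates)
    if (is.null(feature_names)) {
      feature_names <- paste0("x", seq_len(ncol(covariates)))
    }
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(feature_names) != ncol(covariates)) {
    stop("feature_names length must equal the number of covariate columns")
  }
  colnames(covariates) <- feature_names
  structure(
    list(times = times, events = as.integer(events), covariates = covariates,
         name = name),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset '%s'> n = %d, p = %d, events = %d (%.0f%% censored)\n",
              x$name, n_subjects(x), n_features(x), sum(x$events),
              100 * mean(x$events == 0)))
  invisible(x)
}

n_subjects <- function(data) length(data$times)
n_features <- function(data) ncol(data$covariates)

#' Load a survival dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row, extracts the named time and event
#' columns and treats every remaining column as a numeric covariate. Rows
#' with any missing value are dropped with a warning giving the count.
#'
#' @param path Path to a delimited file; the separator is inferred from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param time_col,event_col Names of the time and event columns.
#' @param sep Optional field separator override.
#' @param name Dataset label; defaults to the file name.
#' @return A [survival_dataset()].
#' @export
load_dataset <- function(path, time_col = "time", event_col = "event",
                         sep = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  }
  cov_cols <- setdiff(names(df), c(time_col, event_col))
  if (length(cov_cols) == 0L) stop("no covariate columns in ", path)
  for (col in cov_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      if (any(is.na(coerced) & !is.na(v))) {
        stop("covariate column '", col, "' is not numeric")
      }
      df[[col]] <- coerced
    }
  }
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    warning(sum(!complete), " row(s) with missing values dropped from ", path)
    df <- df[complete, , drop = FALSE]
  }
  survival_dataset(df[[time_col]], df[[event_col]],
                   as.matrix(df[cov_cols]),
                   name = if (is.null(name)) basename(path) else name)
}

#' Write a survival dataset to a delimited text file
#'
#' Inverse of [load_dataset()]: emits a header row with the time and event
#' columns followed by the covariates.
#'
#' @param data A [survival_dataset()].
#' @param path Output path; separator inferred as in [load_dataset()].
#' @param time_col,event_col Column names to use.
#' @export
write_dataset <- function(data, path, time_col = "time", event_col = "event") {
  df <- data.frame(data$times, data$events, data$covariates,
                   check.names = FALSE)
  names(df)[1:2] <- c(time_col, event_col)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a survival dataset
#'
#' @param data A [survival_dataset()].
#' @param rows Optional row index vector.
#' @param features Optional character vector of feature names to keep.
#' @return A [survival_dataset()] restricted to the requested rows/features.
#' @export
subset_dataset <- function(data, rows = NULL, features = NULL) {
  if (is.null(rows)) rows <- seq_len(n_subjects(data))
  X <- data$covariates[rows, , drop = FALSE]
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing)) {
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    }
    X <- X[, features, drop = FALSE]
  }
  survival_dataset(data$times[rows], data$events[rows], X, name = data$name)
}

#' Stratified train/test split
#'
#' Partitions the rows into disjoint train and test sets, stratified on the
#' event indicator so that the event proportion in each part stays within one
#' event of proportional allocation. Errors if either part would contain no
#' event.
#'
#' @param data A [survival_dataset()].
#' @param test_fraction Fraction of rows assigned to the test part, in (0, 1).
#' @param seed Integer seed; the partition is reproducible given the seed.
#' @return A list with elements `train` and `test`, both [survival_dataset()]s,
#'   plus `test_rows`, the test row indices in the original data.
#' @export
split_train_test <- function(data, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  n <- n_subjects(data)
  ev_idx <- which(data$events == 1)
  cs_idx <- which(data$events == 0)
  n_test <- round(test_fraction * n)
  n_test_ev <- round(test_fraction * length(ev_idx))
  n_test_ev <- max(0L, min(n_test_ev, length(ev_idx)))
  n_test_cs <- max(0L, min(n_test - n_test_ev, length(cs_idx)))
  if (n_test_ev < 1L || (length(ev_idx) - n_test_ev) < 1L) {
    stop("split would leave a part with zero events (", length(ev_idx),
         " events total, ", n_test_ev, " allocated to test)")
  }
  test_rows <- with_seed(seed, {
    sort(c(sample(ev_idx, n_test_ev), sample(cs_idx, n_test_cs)))
  })
  list(train = subset_dataset(data, setdiff(seq_len(n), test_rows)),
       test = subset_dataset(data, test_rows),
       test_rows = test_rows)
}

#' Simulation configuration for the synthetic survival generator
#'
#' @param n Sample size.
#' @param p Number of covariates.
#' @param n_informative Number of nonzero entries of the generating
#'   coefficient vector.
#' @param beta_magnitude Absolute effect size of the informative coefficients
#'   (signs alternate).
#' @param baseline_shape,baseline_scale Weibull baseline-hazard parameters:
#'   cumulative baseline hazard \eqn{H_0(t) = (t / scale)^{shape}}.
#' @param censor_rate Target expected fraction of censored subjects in
#'   \eqn{[0, 1)}; 0 disables censoring.
#' @param correlation Exchangeable pairwise covariate correlation in `[0, 1)`.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n = 200L, p = 50L, n_informative = 5L,
                              beta_magnitude = 1, baseline_shape = 1.5,
                              baseline_scale = 1, censor_rate = 0.3,
                              correlation = 0.2, seed = 1L) {
  stopifnot(n >= 2, p >= 1, n_informative >= 0, n_informative <= p,
            beta_magnitude >= 0, baseline_shape > 0, baseline_scale > 0,
            censor_rate >= 0, censor_rate < 1,
            correlation >= 0, correlation < 1)
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_informative = as.integer(n_informative),
                 beta_magnitude = beta_magnitude,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censor_rate = censor_rate, correlation = correlation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a high-dimensional survival dataset
#'
#' Draws covariates from an exchangeable-correlation multivariate normal,
#' event times from a Weibull proportional-hazards model with a sparse linear
#' predictor, and independent exponential censoring whose rate is calibrated
#' by root-finding so the expected censoring fraction matches
#' `config$censor_rate`.
#'
#' The generating coefficients put `n_informative` entries of size
#' `beta_magnitude` (alternating sign) on the first covariates and zeros
#' elsewhere; they are returned for support-recovery experiments.
#'
#' @param config A [simulation_config()].
#' @return A list with `data` (a [survival_dataset()]) and `true_beta`
#'   (named numeric vector of generating coefficients).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n; p <- config$p
    rho <- config$correlation
    # exchangeable correlation: x_j = sqrt(rho) z0 + sqrt(1-rho) z_j
    z0 <- stats::rnorm(n)
    X <- sqrt(rho) * matrix(z0, n, p) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    beta <- numeric(p)
    if (config$n_informative > 0) {
      signs <- rep_len(c(1, -1), config$n_informative)
      beta[seq_len(config$n_informative)] <- signs * config$beta_magnitude
    }
    names(beta) <- colnames(X)
    eta <- drop(X %*% beta)
    # Weibull PH: H0(t) = (t/b)^k, so T = b * (-log U / exp(eta))^(1/k)
    u <- stats::runif(n)
    T_event <- config$baseline_scale *
      (-log(u) / exp(eta))^(1 / config$baseline_shape)
    if (config$censor_rate <= 0) {
      times <- T_event
      events <- rep(1L, n)
    } else {
      # exponential censoring C ~ Exp(c): E[fraction censored] given the
      # drawn T sample is mean(1 - exp(-c T)); solve for c.
      target <- config$censor_rate
      f <- function(cc) mean(1 - exp(-cc * T_event)) - target
      upper <- 1 / stats::median(T_event)
      it <- 0L
      while (f(upper) < 0 && it < 200L) { upper <- upper * 2; it <- it + 1L }
      if (f(upper) < 0) {
        stop(sprintf(
          "censoring calibration failed: achieved rate %.3f < target %.3f",
          mean(1 - exp(-upper * T_event)), target))
      }
      rate <- stats::uniroot(f, lower = 1e-12, upper = upper,
                             tol = 1e-10)$root
      C <- stats::rexp(n, rate = rate)
      times <- pmin(T_event, C)
      events <- as.integer(T_event <= C)
      if (sum(events) < 1) {
        stop("simulated dataset has no events; lower censor_rate")
      }
    }
    list(data = survival_dataset(times, events, X,
                                 name = sprintf("sim(n=%d,p=%d)", n, p)),
         true_beta = beta)
  })
}
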