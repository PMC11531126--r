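# Component-wise likelihood-based boosting for the Cox model: each step
# fits a univariate least-squares learner per column to the current negative
# gradient (martingale residuals), updates the single best column by a
# fraction nu of its least-squares coefficient, and repeats m_stop times.
# m_stop is chosen by seeded tenfold cross-validation.

#' Negative gradient of the Cox partial log-likelihood (martingale residuals)
#'
#' \eqn{u_i = \delta_i - \hat H_0(Y_i) e^{X_i'\beta}} with the Breslow
#' baseline at the current coefficients: the working response of
#' component-wise boosting. Sums to zero.
#'
#' @param beta Coefficient vector.
#' @param data A [survival_dataset()].
#' @return The n-vector of martingale residuals.
#' @export
cox_negative_gradient <- function(beta, data) {
  stopifnot(length(beta) == n_features(data), all(is.finite(beta)))
  eta <- drop(data$covariates %*% beta)
  martingale_residuals_eta(eta, data$times, data$events)
}

new_boost_state <- function(p, nu, feature_names) {
  structure(list(beta = stats::setNames(numeric(p), feature_names),
                 m_stop = 0L, nu = nu, selection_trace = integer(0),
                 cv_curve = NULL),
            class = "boost_state")
}

# One boosting step on standardized covariates Xs (helper shared with the
# CV path evaluator). Returns the updated standardized beta and chosen index.
boost_step_std <- function(beta_std, Xs, times, events, nu, col_ss) {
  u <- martingale_residuals_eta(drop(Xs %*% beta_std), times, events)
  xu <- drop(crossprod(Xs, u))
  # RSS_j = u'u - (x_j'u)^2 / (x_j'x_j); argmin RSS = argmax (x_j'u)^2/ss_j
  score <- ifelse(col_ss > 0, xu^2 / col_ss, -Inf)
  j <- which.max(score)   # which.max takes the lowest index on ties
  b_j <- xu[j] / col_ss[j]
  beta_std[j] <- beta_std[j] + nu * b_j
  list(beta = beta_std, j = j)
}

#' One component-wise boosting step
#'
#' Computes the negative gradient at the current coefficients, fits the
#' univariate least-squares coefficient \eqn{\hat b_j = (X_j'X_j)^{-1}X_j'u}
#' for every column of the internally standardized covariates, selects the
#' column minimizing the residual sum of squares (ties broken by the lowest
#' column index; constant columns skipped with a warning), and adds
#' \eqn{\nu \hat b_{j^*}} to that coordinate.
#'
#' @param state A `boost_state` from [fit_coxboost()] (or a fresh state).
#' @param data A [survival_dataset()].
#' @return The updated `boost_state`; `selection_trace` grows by one entry.
#' @export
boost_step <- function(state, data) {
  std <- standardize_columns(data$covariates)
  if (any(std$constant)) {
    warning(sum(std$constant), " constant column(s) skipped in boosting")
  }
  col_ss <- colSums(std$X^2)
  col_ss[std$constant] <- 0
  beta_std <- state$beta * std$scale   # original -> standardized scale
  res <- boost_step_std(beta_std, std$X, data$times, data$events,
                        state$nu, col_ss)
  state$beta <- res$beta / std$scale
  state$m_stop <- state$m_stop + 1L
  state$selection_trace <- c(state$selection_trace, res$j)
  state
}

#' Fit the boosting path
#'
#' Runs `m_stop` boosting steps from \eqn{\beta = 0}; deterministic given
#' the data. The number of distinct selected features is at most `m_stop`.
#'
#' @param data A [survival_dataset()].
#' @param m_stop Number of boosting steps (>= 0).
#' @param nu Step length in (0, 1]; default 0.1.
#' @return A `boost_state` with original-scale `beta`, `selection_trace`
#'   (column indices chosen per step) and `nu`.
#' @export
fit_coxboost <- function(data, m_stop = 100L, nu = 0.1) {
  stopifnot(m_stop >= 0, nu >= 0, nu <= 1)
  std <- standardize_columns(data$covariates)
  if (any(std$constant)) {
    warning(sum(std$constant), " constant column(s) skipped in boosting")
  }
  col_ss <- colSums(std$X^2)
  col_ss[std$constant] <- 0
  p <- ncol(std$X)
  beta_std <- numeric(p)
  trace <- integer(m_stop)
  for (m in seq_len(m_stop)) {
    res <- boost_step_std(beta_std, std$X, data$times, data$events, nu,
                          col_ss)
    beta_std <- res$beta
    trace[m] <- res$j
  }
  state <- new_boost_state(p, nu, colnames(data$covariates))
  state$beta <- stats::setNames(beta_std / std$scale,
                                colnames(data$covariates))
  state$m_stop <- as.integer(m_stop)
  state$selection_trace <- trace
  state
}

#' Cross-validated choice of the number of boosting steps
#'
#' For each of `n_folds` seeded, event-stratified folds the boosting path is
#' fitted on the complement and the held-out partial-likelihood deviance
#' (Verweij-van Houwelingen form: full-data minus complement log partial
#' likelihood at the path coefficients) is evaluated incrementally at every
#' candidate `m`. Returns the `m` minimizing the mean deviance.
#'
#' @param data A [survival_dataset()].
#' @param nu Step length.
#' @param m_grid Increasing candidate step counts (default `0:200`).
#' @param n_folds Number of folds (default 10).
#' @param seed Fold seed.
#' @return Integer `m_stop`; the CV curve is attached as attribute
#'   `cv_curve` (mean deviance per candidate).
#' @export
select_mstop_cv <- function(data, nu = 0.1, m_grid = 0:200, n_folds = 10L,
                            seed = 1L) {
  stopifnot(length(m_grid) >= 1, !is.unsorted(m_grid))
  folds <- make_folds(data$events, n_folds, seed)
  m_max <- max(m_grid)
  dev <- matrix(0, length(m_grid), n_folds)
  for (k in seq_len(n_folds)) {
    train <- subset_dataset(data, which(folds != k))
    std <- standardize_columns(train$covariates)
    col_ss <- colSums(std$X^2)
    col_ss[std$constant] <- 0
    beta_std <- numeric(ncol(std$X))
    # original-scale beta at m = 0
    grid_pos <- 1L
    record <- function(beta_std, m) {
      beta <- beta_std / std$scale
      ll_all <- -neg_log_partial_likelihood(beta, data) * n_subjects(data)
      ll_tr <- -neg_log_partial_likelihood(beta, train) * n_subjects(train)
      -2 * (ll_all - ll_tr)
    }
    for (m in 0:m_max) {
      if (grid_pos <= length(m_grid) && m == m_grid[grid_pos]) {
        dev[grid_pos, k] <- record(beta_std, m)
        grid_pos <- grid_pos + 1L
      }
      if (m == m_max) break
      beta_std <- boost_step_std(beta_std, std$X, train$times, train$events,
                                 nu, col_ss)$beta
    }
  }
  curve <- rowMeans(dev)
  best <- as.integer(m_grid[which.min(curve)])
  attr(best, "cv_curve") <- curve
  best
}

#' CoxBoost feature selection
#'
#' Chooses `m_stop` by cross-validation, fits the boosting path, and returns
#' the features with nonzero boosted coefficients, scored by `|beta|`.
#'
#' @param data A [survival_dataset()].
#' @param nu Step length (default 0.1).
#' @param m_grid Candidate step counts (default `0:200`).
#' @param n_folds CV folds (default 10).
#' @param seed Fold seed.
#' @return A [feature_set()].
#' @export
coxboost_select <- function(data, nu = 0.1, m_grid = 0:200, n_folds = 10L,
                            seed = 1L) {
  m_stop <- select_mstop_cv(data, nu, m_grid, n_folds, seed)
  state <- fit_coxboost(data, as.integer(m_stop), nu)
  score <- abs(state$beta)
  keep <- names(score)[score > 0]
  if (length(keep) == 0L) {
    message("coxboost selection is empty at m_stop = ", as.integer(m_stop))
  }
  # fallback ranking when nothing was selected: first-step gradient scores
  all_scores <- if (all(score == 0)) {
    std <- standardize_columns(data$covariates)
    u0 <- martingale_residuals_eta(rep(0, n_subjects(data)), data$times,
                                   data$events)
    stats::setNames(abs(drop(crossprod(std$X, u0))), names(score))
  } else score
  fs <- feature_set(keep, method = "coxboost",
                    tuning = list(m_stop = as.integer(m_stop), nu = nu,
                                  n_folds = n_folds),
                    scores = score[keep], all_scores = all_scores)
  attr(fs, "boost_state") <- state
  fs
}

#' Serialize a boosting state to JSON
#'
#' @param state A `boost_state`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
boost_state_to_json <- function(state, path = NULL) {
  obj <- list(nu = state$nu, m_stop = state$m_stop,
              trace = state$selection_trace,
              beta_by_name = as.list(state$beta[state$beta != 0]),
              cv_curve = state$cv_curve)
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else { jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
         invisible(path) }
}
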