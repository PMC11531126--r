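# L1 (lasso) and SCAD penalized Cox regression by cyclic coordinate descent
# on the iteratively reweighted quadratic approximation of the partial
# likelihood; SCAD solved by local linear approximation (LLA) from the lasso
# solution. Covariates are standardized internally (selection is decided on
# the standardized scale); reported coefficients are on the original scale.

#' Penalty configuration for penalized Cox selection
#'
#' @param penalty_kind `"lasso"` or `"scad"`.
#' @param lambda_grid Optional decreasing positive grid; if `NULL` a 50-point
#'   log-spaced grid from the data-derived \eqn{\lambda_{max}} down to
#'   \eqn{0.01 \lambda_{max}} is built at fit time.
#' @param scad_a SCAD shape parameter, must exceed 2 (default 3.7).
#' @param n_folds Cross-validation folds (default 10).
#' @param zero_tol Coefficients below this magnitude (standardized scale)
#'   count as zero (default 1e-8).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `penalty_config`.
#' @export
penalty_config <- function(penalty_kind = c("lasso", "scad"),
                           lambda_grid = NULL, scad_a = 3.7,
                           n_folds = 10L, zero_tol = 1e-8, seed = 1L) {
  penalty_kind <- match.arg(penalty_kind)
  if (scad_a <= 2) stop("scad_a must exceed 2")
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || any(diff(lambda_grid) >= 0)) {
      stop("lambda_grid must be strictly decreasing and positive")
    }
  }
  structure(list(penalty_kind = penalty_kind, lambda_grid = lambda_grid,
                 scad_a = scad_a, n_folds = as.integer(n_folds),
                 zero_tol = zero_tol, seed = as.integer(seed)),
            class = "penalty_config")
}

#' First derivative of the SCAD penalty
#'
#' \eqn{p'_\lambda(\beta) = \lambda} for \eqn{\beta \le \lambda};
#' \eqn{(a\lambda - \beta)_+ / (a - 1)} for \eqn{\beta > \lambda}; zero
#' beyond \eqn{a\lambda}. Continuous in \eqn{\beta}, flat at \eqn{\lambda}
#' near the origin so small coefficients are shrunk like the lasso while
#' large ones escape the bias.
#'
#' @param beta_abs Non-negative coefficient magnitude(s).
#' @param lambda Positive tuning parameter.
#' @param a Shape parameter, must exceed 2 (conventional value 3.7).
#' @return Derivative value(s), vectorized over `beta_abs`.
#' @export
scad_derivative <- function(beta_abs, lambda, a = 3.7) {
  if (a <= 2) stop("SCAD requires a > 2")
  stopifnot(lambda > 0, all(beta_abs >= 0))
  ifelse(beta_abs <= lambda, lambda,
         pmax(a * lambda - beta_abs, 0) / (a - 1))
}

# SCAD penalty primitive P_lambda(|beta|): the integral of scad_derivative
# from 0, in closed form per branch.
scad_penalty <- function(beta_abs, lambda, a = 3.7) {
  if (a <= 2) stop("SCAD requires a > 2")
  b <- abs(beta_abs)
  out <- numeric(length(b))
  small <- b <= lambda
  mid <- b > lambda & b < a * lambda
  big <- b >= a * lambda
  out[small] <- lambda * b[small]
  out[mid] <- -(b[mid]^2 - 2 * a * lambda * b[mid] + lambda^2) /
    (2 * (a - 1))
  out[big] <- (a + 1) * lambda^2 / 2
  out
}

#' Penalized negative log partial likelihood
#'
#' [neg_log_partial_likelihood()] plus the summed penalty
#' \eqn{\sum_j P_\lambda(|\beta_j|)}: the L1 penalty \eqn{\lambda |\beta|}
#' or the SCAD primitive obtained by integrating its first derivative
#' from zero.
#'
#' @param beta Coefficient vector (the scale it is evaluated on is the
#'   caller's responsibility; the fitter works on standardized covariates).
#' @param data A [survival_dataset()].
#' @param config A [penalty_config()].
#' @param lambda Non-negative tuning parameter.
#' @return The scalar penalized objective.
#' @export
penalized_objective <- function(beta, data, config, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  nll <- neg_log_partial_likelihood(beta, data)
  if (lambda == 0) return(nll)
  pen <- if (config$penalty_kind == "lasso") {
    lambda * sum(abs(beta))
  } else {
    sum(scad_penalty(abs(beta), lambda, config$scad_a))
  }
  nll + pen
}

# Data-derived lambda_max: the smallest lambda at which the lasso solution
# is exactly 0, i.e. max_j |x_j' u(0)| / n on standardized columns.
lambda_max_value <- function(Xs, times, events) {
  u0 <- martingale_residuals_eta(rep(0, length(times)), times, events)
  max(abs(drop(crossprod(Xs, u0)))) / length(times)
}

default_lambda_grid <- function(lmax, n_lambda = 50L, ratio = 0.01) {
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# Gradient and full Hessian of the mean negative log partial likelihood at
# eta = Xs beta, assembled in O(np + K p^2): the Hessian is
# X' diag(w_i A_i) X - Q' diag(d) Q with Q the K x p matrix of risk-set
# weighted covariate means at the distinct event times.
cox_grad_hess <- function(Xs, times, events, beta) {
  n <- nrow(Xs)
  eta <- drop(Xs %*% beta)
  shift <- max(eta)
  w <- exp(eta - shift)
  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]
  Xo <- Xs[ord, , drop = FALSE]
  wo <- w[ord]
  RS0 <- rev(cumsum(rev(wo)))
  RS1 <- apply(Xo * wo, 2L, function(col) rev(cumsum(rev(col))))
  ev_t <- tt[ee == 1]
  event_times <- unique(ev_t)
  d <- tabulate(match(ev_t, event_times), nbins = length(event_times))
  first <- match(event_times, tt)
  S0 <- RS0[first]
  Q <- RS1[first, , drop = FALSE] / S0
  # per-subject cumulative hazard at Y_i (shifted scale) for diag weights
  cumA <- cumsum(d / S0)
  idx <- findInterval(times, event_times)
  A <- ifelse(idx > 0, cumA[pmax(idx, 1L)], 0)
  u <- events - A * w                                  # martingale residuals
  grad <- -drop(crossprod(Xs, u)) / n
  H <- (crossprod(Xs, Xs * (w * A)) - crossprod(Q * sqrt(d))) / n
  list(grad = grad, hess = H)
}

# Core penalized solver on STANDARDIZED covariates with per-coefficient
# penalty factors `pf` (all 1 for plain lasso; LLA weights for SCAD).
# Proximal-Newton: coordinate descent on the exact quadratic expansion of
# the partial likelihood (full Hessian for p <= hess_p_max, diagonal
# surrogate above that), with a monotone line search (halving, then
# doubling) on the true penalized objective.
penalized_cox_l1 <- function(Xs, times, events, lambda, pf,
                             beta_init = NULL, zero_tol = 1e-8,
                             max_outer = 100L, tol = 1e-9,
                             hess_p_max = 500L) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  obj_fun <- function(b) {
    neg_log_pl_eta(drop(Xs %*% b), times, events) + lambda * sum(pf * abs(b))
  }
  obj <- obj_fun(beta)
  done <- FALSE
  full_hessian <- p <= hess_p_max
  for (outer in seq_len(max_outer)) {
    if (full_hessian) {
      gh <- cox_grad_hess(Xs, times, events, beta)
      b_new <- cd_quad_l1_cpp(gh$hess, gh$grad, beta, lambda, pf, beta,
                              1e-9, 200L)
    } else {
      eta <- drop(Xs %*% beta)
      rq <- cox_risk_quantities(eta, times, events)
      u <- events - rq$A * rq$w                     # martingale residuals
      w <- (rq$A * rq$w - rq$B * rq$w^2) / n        # diagonal Hessian / n
      w <- pmax(w, 1e-9)
      z <- eta + u / (n * w)
      b_new <- cd_wls_l1_cpp(Xs, w, z, lambda, pf, beta, 1e-7, 50L)
    }
    dir <- b_new - beta
    # monotone line search on the true objective: halve on increase,
    # expand while it keeps decreasing (diagonal steps under-shoot)
    step <- 1
    cand <- b_new
    cand_obj <- obj_fun(cand)
    if (cand_obj <= obj + 1e-12) {
      while (step < 16) {
        trial <- beta + 2 * step * dir
        trial_obj <- obj_fun(trial)
        if (trial_obj < cand_obj - 1e-14) {
          step <- 2 * step; cand <- trial; cand_obj <- trial_obj
        } else break
      }
    } else {
      while (cand_obj > obj + 1e-12 && step > 1e-8) {
        step <- step / 2
        cand <- beta + step * dir
        cand_obj <- obj_fun(cand)
      }
      if (cand_obj > obj + 1e-12) { cand <- beta; cand_obj <- obj }
    }
    moved <- max(abs(cand - beta))
    done <- abs(obj - cand_obj) < tol * max(abs(obj), 1) && moved < 1e-5
    beta <- cand; obj <- cand_obj
    if (done) break
  }
  if (!done) {
    warning("penalized Cox fit reached ", max_outer,
            " outer cycles without converging; returning best iterate")
  }
  beta[abs(beta) < zero_tol] <- 0
  list(beta = beta, objective = obj, n_outer = outer)
}

#' Fit a penalized Cox model at a fixed lambda
#'
#' Lasso: cyclic coordinate descent with soft-thresholding on the quadratic
#' approximation of the partial likelihood. SCAD: local linear approximation
#' -- iteratively reweighted lasso with weights
#' \eqn{p'_\lambda(|\beta_j^{(k)}|)/\lambda}, initialized at the lasso
#' solution and iterated for 5 reweightings.
#'
#' @param data A [survival_dataset()].
#' @param config A [penalty_config()].
#' @param lambda Non-negative tuning parameter.
#' @param beta_init Optional warm-start vector on the standardized scale.
#' @return A `cox_fit` whose `beta` is on the original covariate scale, with
#'   extra fields `lambda`, `beta_std` (standardized-scale coefficients used
#'   for the selection decision) and `n_nonzero`.
#' @export
fit_penalized_cox <- function(data, config, lambda, beta_init = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  std <- standardize_columns(data$covariates)
  Xs <- std$X
  times <- data$times; events <- data$events
  p <- ncol(Xs)
  pf <- rep(1, p)
  fit <- penalized_cox_l1(Xs, times, events, lambda, pf,
                          beta_init = beta_init,
                          zero_tol = config$zero_tol)
  if (config$penalty_kind == "scad" && lambda > 0) {
    for (k in seq_len(5L)) {
      pf_new <- scad_derivative(abs(fit$beta), lambda, config$scad_a) / lambda
      if (max(abs(pf_new - pf)) < 1e-10) break  # LLA weights stabilized
      pf <- pf_new
      fit <- penalized_cox_l1(Xs, times, events, lambda, pf,
                              beta_init = fit$beta,
                              zero_tol = config$zero_tol)
    }
  }
  beta_std <- fit$beta
  beta <- beta_std / std$scale
  beta[std$constant] <- 0
  names(beta) <- colnames(data$covariates)
  bl <- breslow_baseline(beta, data)
  structure(list(beta = beta, beta_std = stats::setNames(beta_std, names(beta)),
                 baseline_times = bl$baseline_times,
                 baseline_cumhaz = bl$baseline_cumhaz,
                 n_iter = fit$n_outer, converged = fit$n_outer < 200L,
                 log_partial_likelihood =
                   -neg_log_partial_likelihood(beta, data),
                 lambda = lambda,
                 n_nonzero = sum(abs(beta_std) >= config$zero_tol)),
            class = "cox_fit")
}

#' Cross-validated selection of lambda
#'
#' Verweij-van Houwelingen cross-validated partial-likelihood deviance:
#' for each fold the model is fitted on the complement and the fold's
#' contribution is the full-data log partial likelihood minus the
#' complement's, both at the fold fit. Folds are stratified on the event
#' indicator and seeded; a fold layout leaving a training part without
#' events is redrawn (up to 10 attempts).
#'
#' @param data A [survival_dataset()].
#' @param config A [penalty_config()].
#' @return The lambda from the grid minimizing the CV deviance. The grid and
#'   per-lambda CV curve are attached as attributes `lambda_grid` and
#'   `cv_deviance`.
#' @export
select_lambda_cv <- function(data, config) {
  std <- standardize_columns(data$covariates)
  lmax <- lambda_max_value(std$X, data$times, data$events)
  grid <- if (is.null(config$lambda_grid)) default_lambda_grid(lmax)
          else config$lambda_grid
  folds <- make_folds(data$events, config$n_folds, config$seed)
  # unnormalized log PL helper (sum scale, so contributions add over folds)
  logpl <- function(beta, d) {
    -neg_log_partial_likelihood(beta, d) * n_subjects(d)
  }
  cv <- matrix(0, length(grid), config$n_folds)
  for (k in seq_len(config$n_folds)) {
    train <- subset_dataset(data, which(folds != k))
    beta_warm <- NULL
    for (li in seq_along(grid)) {
      fitk <- fit_penalized_cox(train, config, grid[li],
                                beta_init = beta_warm)
      beta_warm <- fitk$beta_std
      # deviance contribution: -2 [ l_full(beta_k) - l_train(beta_k) ]
      cv[li, k] <- -2 * (logpl(fitk$beta, data) - logpl(fitk$beta, train))
    }
  }
  curve <- rowMeans(cv)
  best <- grid[which.min(curve)]
  attr(best, "lambda_grid") <- grid
  attr(best, "cv_deviance") <- curve
  best
}

# Shared selector body for lasso_select / scad_select.
penalized_select <- function(data, config) {
  lambda <- select_lambda_cv(data, config)
  fit <- fit_penalized_cox(data, config, as.numeric(lambda))
  score <- abs(fit$beta_std)
  keep <- names(score)[score >= config$zero_tol]
  if (length(keep) == 0L) {
    message(config$penalty_kind, " selection is empty at lambda = ",
            signif(as.numeric(lambda), 4))
  }
  feature_set(keep, method = paste0(config$penalty_kind, "_cox"),
              tuning = list(lambda = as.numeric(lambda),
                            n_folds = config$n_folds,
                            scad_a = if (config$penalty_kind == "scad")
                              config$scad_a else NULL),
              scores = score[keep], all_scores = score)
}

#' LASSO-Cox feature selection
#'
#' Cross-validates lambda, fits the L1-penalized Cox model at the selected
#' value, and returns the features with nonzero standardized coefficients.
#'
#' @param data A [survival_dataset()].
#' @param config A [penalty_config()]; its `penalty_kind` is forced to
#'   `"lasso"`.
#' @return A [feature_set()].
#' @export
lasso_select <- function(data, config = penalty_config("lasso")) {
  config$penalty_kind <- "lasso"
  penalized_select(data, config)
}

#' SCAD-Cox feature selection
#'
#' As [lasso_select()] but with the smoothly clipped absolute deviation
#' penalty (a = 3.7 by default), fitted by local linear approximation from
#' the lasso start.
#'
#' @param data A [survival_dataset()].
#' @param config A [penalty_config()]; its `penalty_kind` is forced to
#'   `"scad"`.
#' @return A [feature_set()].
#' @export
scad_select <- function(data, config = penalty_config("scad")) {
  config$penalty_kind <- "scad"
  penalized_select(data, config)
}
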