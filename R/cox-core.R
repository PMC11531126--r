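# Cox proportional-hazards machinery shared by every selector and by the
# CoxPH predictor. Ties are handled with the Breslow approximation
# throughout: tied events share one risk-set denominator, and the baseline
# cumulative hazard is the Breslow estimator.

# Risk-set bookkeeping used by the likelihood, gradient and baseline code.
# Returns, per distinct event time t_k (ascending): d_k (events at t_k),
# S0_k = sum_{l in R_k} exp(eta_l), plus per-subject sums
# A_i = sum_{t_k <= Y_i} d_k / S0_k  (Breslow cumulative hazard at Y_i)
# B_i = sum_{t_k <= Y_i} d_k / S0_k^2 (for the diagonal Hessian).
cox_risk_quantities <- function(eta, times, events) {
  # center eta before exponentiation for overflow safety; S0 ratios are
  # invariant, H0 increments scale back by exp(shift)
  shift <- max(eta)
  w <- exp(eta - shift)
  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]; ww <- w[ord]
  # reverse cumulative sum of weights = at-risk sum at each sorted position
  rev_cum <- rev(cumsum(rev(ww)))
  ev_pos <- which(ee == 1)
  ev_t <- tt[ev_pos]
  uniq <- !duplicated(ev_t)
  event_times <- ev_t[uniq]
  d <- as.numeric(tabulate(match(ev_t, event_times), nbins = length(event_times)))
  # S0 at an event time = at-risk sum at the first sorted position with that time
  first_any <- match(event_times, tt)
  S0 <- rev_cum[first_any]          # still on the shifted scale
  # per-subject cumulative sums over event times <= Y_i
  incA <- d / S0
  incB <- d / S0^2
  cumA <- cumsum(incA)
  cumB <- cumsum(incB)
  idx <- findInterval(times, event_times)
  A <- ifelse(idx > 0, cumA[pmax(idx, 1L)], 0)
  B <- ifelse(idx > 0, cumB[pmax(idx, 1L)], 0)
  list(event_times = event_times, d = d, S0 = S0, shift = shift,
       A = A, B = B, w = w)
}

#' Negative log partial likelihood of the Cox model
#'
#' Computes \eqn{-\ell_n(\beta) = -(1/n)\sum_{i \in D} [X_i'\beta - \log
#' \sum_{l \in R_i} \exp(X_l'\beta)]} with Breslow handling of tied event
#' times (tied events share the risk-set denominator). Linear predictors are
#' centered by their maximum before exponentiation.
#'
#' @param beta Coefficient vector of length `p`.
#' @param data A [survival_dataset()].
#' @return The scalar negative mean log partial likelihood.
#' @export
neg_log_partial_likelihood <- function(beta, data) {
  stopifnot(length(beta) == n_features(data), all(is.finite(beta)))
  eta <- drop(data$covariates %*% beta)
  neg_log_pl_eta(eta, data$times, data$events)
}

# eta-parameterized version, also used by the boosting and penalized modules.
neg_log_pl_eta <- function(eta, times, events) {
  rq <- cox_risk_quantities(eta, times, events)
  # log S0 on the original scale = log(S0_shifted) + shift
  ll <- sum(eta[events == 1]) - sum(rq$d * (log(rq$S0) + rq$shift))
  out <- -ll / length(times)
  if (!is.finite(out)) stop("non-finite partial likelihood")
  out
}

# Martingale residuals u_i = delta_i - H0(Y_i) exp(eta_i): the per-subject
# negative gradient of the (unnormalized) negative log partial likelihood
# with respect to a subject offset.
martingale_residuals_eta <- function(eta, times, events) {
  rq <- cox_risk_quantities(eta, times, events)
  events - rq$A * rq$w   # A is on the shifted scale, w = exp(eta - shift)
}

# Analytic gradient of neg_log_partial_likelihood w.r.t. beta: -(1/n) X'u.
neg_log_pl_gradient <- function(beta, data) {
  eta <- drop(data$covariates %*% beta)
  u <- martingale_residuals_eta(eta, data$times, data$events)
  -drop(crossprod(data$covariates, u)) / n_subjects(data)
}

#' Breslow baseline cumulative hazard
#'
#' \eqn{\hat H_0(t) = \sum_{t_k \le t} d_k / \sum_{l \in R_k}
#' \exp(X_l'\beta)}, a right-continuous non-decreasing step function over the
#' distinct event times.
#'
#' @param beta Coefficient vector.
#' @param data A [survival_dataset()].
#' @return A list with `baseline_times` (distinct event times, ascending) and
#'   `baseline_cumhaz` (cumulative hazard at those times).
#' @export
breslow_baseline <- function(beta, data) {
  stopifnot(length(beta) == n_features(data), all(is.finite(beta)))
  eta <- drop(data$covariates %*% beta)
  rq <- cox_risk_quantities(eta, data$times, data$events)
  inc <- rq$d / (rq$S0 * exp(rq$shift))
  list(baseline_times = rq$event_times, baseline_cumhaz = cumsum(inc))
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Breslow partial likelihood with Newton steps and
#' step-halving; convergence when the relative objective change falls below
#' `1e-9` or the gradient max-norm below `1e-6`, up to `max_iter` iterations.
#' A small ridge term can stabilize a near-singular information matrix.
#'
#' @param data A [survival_dataset()].
#' @param ridge_eps Non-negative ridge stabilizer added to the information
#'   diagonal (default `1e-8`).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit`: `beta` (named), `baseline_times`,
#'   `baseline_cumhaz`, `n_iter`, `converged`, `log_partial_likelihood`
#'   (mean log PL at the solution).
#' @export
fit_cox <- function(data, ridge_eps = 1e-8, max_iter = 100L) {
  stopifnot(ridge_eps >= 0)
  X <- data$covariates
  n <- n_subjects(data); p <- n_features(data)
  beta <- numeric(p)
  obj <- neg_log_partial_likelihood(beta, data)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- neg_log_pl_gradient(beta, data)
    if (max(abs(grad)) < 1e-6) { converged <- TRUE; break }
    H <- cox_information(beta, data) / n
    diag(H) <- diag(H) + ridge_eps
    step <- tryCatch(solve(H, -grad), error = function(e) {
      solve(H + diag(1e-6, p), -grad)
    })
    # step-halving line search on the objective
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      cand_obj <- tryCatch(neg_log_partial_likelihood(cand, data),
                           error = function(e) Inf)
      if (cand_obj <= obj + 1e-14) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { cand <- beta; cand_obj <- obj; break }
    }
    rel <- abs(obj - cand_obj) / max(abs(obj), 1e-12)
    beta <- cand; obj <- cand_obj
    if (rel < 1e-9) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Cox fit did not converge in ", max_iter, " iterations")
  }
  if (max(abs(beta)) > 50) {
    warning("coefficient norm exceeds 50: possible monotone likelihood ",
            "(perfect separation)")
  }
  bl <- breslow_baseline(beta, data)
  names(beta) <- colnames(X)
  structure(list(beta = beta, baseline_times = bl$baseline_times,
                 baseline_cumhaz = bl$baseline_cumhaz, n_iter = iter,
                 converged = converged, log_partial_likelihood = -obj),
            class = "cox_fit")
}

# Full observed information of the (1/1) log PL: sum over event times of
# d_k [ S2/S0 - (S1/S0)(S1/S0)' ]. Used only at p modest (Newton fitter).
cox_information <- function(beta, data) {
  X <- data$covariates
  times <- data$times; events <- data$events
  eta <- drop(X %*% beta)
  shift <- max(eta)
  w <- exp(eta - shift)
  event_times <- sort(unique(times[events == 1]))
  p <- ncol(X)
  H <- matrix(0, p, p)
  # iterate distinct event times from latest to earliest, growing risk set
  ord <- order(times, decreasing = TRUE)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  pos <- 1L
  nn <- length(times)
  for (k in rev(seq_along(event_times))) {
    tk <- event_times[k]
    while (pos <= nn && times[ord[pos]] >= tk) {
      i <- ord[pos]
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * X[i, ]
      S2 <- S2 + w[i] * tcrossprod(X[i, ])
      pos <- pos + 1L
    }
    d_k <- sum(events == 1 & times == tk)
    xbar <- S1 / S0
    H <- H + d_k * (S2 / S0 - tcrossprod(xbar))
  }
  H
}

#' Predict survival curves from a Cox fit
#'
#' \eqn{\hat S(t \mid x) = \exp(-\hat H_0(t) e^{x'\beta})} with the Breslow
#' baseline as a right-continuous step function; values clipped to `[0, 1]`.
#'
#' @param fit A `cox_fit` from [fit_cox()].
#' @param X_new Numeric matrix of new covariate rows (columns matching the
#'   training features).
#' @param eval_times Non-negative, sorted evaluation grid.
#' @return An object of class `surv_curves`: `eval_times` and `surv`, an
#'   `nrow(X_new) x length(eval_times)` matrix with non-increasing rows.
#' @export
predict_survival <- function(fit, X_new, eval_times) {
  stopifnot(inherits(fit, "cox_fit"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$beta)) {
    stop("X_new has ", ncol(X_new), " columns but the fit expects ",
         length(fit$beta))
  }
  check_eval_times(eval_times)
  H0 <- step_eval(fit$baseline_times, fit$baseline_cumhaz, eval_times)
  lp <- drop(X_new %*% fit$beta)
  S <- exp(-outer(exp(lp), H0))
  surv_curves(eval_times, pmin(pmax(S, 0), 1))
}

check_eval_times <- function(eval_times) {
  if (any(eval_times < 0) || is.unsorted(eval_times)) {
    stop("eval_times must be non-negative and sorted increasing")
  }
}

surv_curves <- function(eval_times, surv) {
  structure(list(eval_times = eval_times, surv = surv),
            class = "surv_curves")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> p = %d, converged = %s in %d iterations, mean logPL = %.6f\n",
              length(x$beta), x$converged, x$n_iter,
              x$log_partial_likelihood))
  invisible(x)
}

#' Serialize a Cox fit to JSON
#'
#' @param fit A `cox_fit`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
cox_fit_to_json <- function(fit, path = NULL) {
  obj <- list(beta = as.list(fit$beta),
              baseline = list(times = fit$baseline_times,
                              cumhaz = fit$baseline_cumhaz),
              converged = fit$converged, n_iter = fit$n_iter)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
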