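# Censoring-aware evaluation metrics: reverse Kaplan-Meier censoring
# estimate, IPCW Brier score and its time integral, concordance index over
# comparable pairs, and KM-referenced integrated absolute/squared error.

#' Reverse Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator with the roles of event and censoring swapped
#' (indicator \eqn{1 - \delta} treated as the "event"), giving \eqn{\hat G(t)
#' = P(C > t)}, the weight denominator of the IPCW Brier score.
#'
#' @param data A [survival_dataset()].
#' @return A list of class `censoring_estimate` with `times` (censoring
#'   times, ascending) and `G_hat` (right-continuous step values;
#'   \eqn{\hat G(0) = 1}).
#' @export
reverse_km <- function(data) {
  fit <- survival::survfit(
    survival::Surv(data$times, 1 - data$events) ~ 1,
    se.fit = FALSE)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], G_hat = fit$surv[keep]),
            class = "censoring_estimate")
}

eval_G <- function(G, at) step_eval(G$times, G$G_hat, at, init = 1)

#' IPCW Brier score at a fixed time
#'
#' Mean over test subjects of the inverse-probability-of-censoring-weighted
#' squared error between event status at `t` and the predicted survival
#' probability \eqn{\hat S(t \mid z_i)}: subjects with an observed event by
#' `t` contribute \eqn{(0 - \hat S)^2 / \hat G(t_i)}, subjects still under
#' observation contribute \eqn{(1 - \hat S)^2 / \hat G(t)}, and subjects
#' censored by `t` contribute nothing. Subjects whose required weight
#' denominator is zero are excluded with a warning.
#'
#' @param surv A `surv_curves` object whose `eval_times` contain `t`.
#' @param test A [survival_dataset()] aligned with the rows of `surv`.
#' @param t Evaluation time.
#' @param G A `censoring_estimate`, typically [reverse_km()] on the test set.
#' @return The scalar Brier score.
#' @export
brier_score <- function(surv, test, t, G = reverse_km(test)) {
  idx <- match(t, surv$eval_times)
  if (is.na(idx)) {
    # off-grid t: right-continuous step lookup on the curves; before the
    # grid no hazard has accrued, so S = 1
    idx <- findInterval(t, surv$eval_times)
  }
  S_t <- if (idx < 1L) rep(1, nrow(surv$surv)) else surv$surv[, idx]
  ti <- test$times; di <- test$events
  n <- length(ti)
  contrib <- numeric(n)
  keep <- rep(TRUE, n)
  event_by_t <- ti <= t & di == 1
  after_t <- ti > t
  G_ti <- eval_G(G, ti)
  G_t <- eval_G(G, t)
  if (any(event_by_t)) {
    bad <- event_by_t & G_ti <= 0
    if (any(bad)) {
      warning(sum(bad), " subject(s) dropped: censoring weight zero at t_i")
      keep[bad] <- FALSE
    }
    ok <- event_by_t & keep
    contrib[ok] <- (0 - S_t[ok])^2 / G_ti[ok]
  }
  if (any(after_t)) {
    if (G_t <= 0) {
      warning(sum(after_t), " subject(s) dropped: censoring weight zero at t")
      keep[after_t] <- FALSE
    } else {
      contrib[after_t] <- (1 - S_t[after_t])^2 / G_t
    }
  }
  sum(contrib[keep]) / sum(keep)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of [brier_score()] over `[0, max(t_i)]`, normalized
#' by `max(t_i)`. The integration grid is zero plus the distinct observed
#' event times of the test set.
#'
#' @inheritParams brier_score
#' @return The scalar IBS in `[0, 1]` (without censoring; IPCW weights can
#'   push single-time scores above 1, the integral is reported as computed).
#' @export
integrated_brier <- function(surv, test, G = reverse_km(test)) {
  t_max <- max(test$times)
  grid <- sort(unique(test$times[test$events == 1]))
  grid <- grid[grid <= t_max]
  if (length(grid) < 1L) stop("no event times to integrate over")
  if (length(grid) == 1L) {
    warning("single event time: returning BS at that time")
    return(brier_score(surv, test, grid, G))
  }
  grid <- c(0, grid)
  bs <- vapply(grid, function(t) brier_score(surv, test, t, G), numeric(1))
  trapezoid(grid, bs) / t_max
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Comparable pairs under right censoring
#'
#' A pair (i, j) with \eqn{t_i < t_j} is comparable iff the earlier subject
#' experienced the event (\eqn{\delta_i = 1}); at tied times the pair is
#' comparable iff exactly one member is an event, the event ordered first.
#' With all subjects uncensored this yields all \eqn{n \choose 2} pairs.
#'
#' @param test A [survival_dataset()] (covariates are ignored).
#' @return A 2-column integer matrix of row indices; column 1 is the
#'   earlier/event member of each pair.
#' @export
comparable_pairs <- function(test) {
  ti <- test$times; di <- test$events
  n <- length(ti)
  out_i <- integer(0); out_j <- integer(0)
  for (i in which(di == 1)) {
    j <- which(ti > ti[i] | (ti == ti[i] & di == 0))
    j <- setdiff(j, i)
    # avoid double-counting event-event ties: handled below
    out_i <- c(out_i, rep.int(i, length(j)))
    out_j <- c(out_j, j)
  }
  cbind(i = out_i, j = out_j)
}

#' Concordance index over comparable pairs
#'
#' Fraction of comparable pairs whose predicted ordering agrees with the
#' observed survival ordering. In `"hazard"` mode `scores` are per-subject
#' risk scores (higher = shorter survival expected) and a pair is concordant
#' when the earlier-event member has the higher score. In `"survival"` mode
#' `scores` is a `surv_curves` object and curves are compared at the median
#' observed event time. Tied predictions count 1/2.
#'
#' @param scores Numeric risk-score vector (`mode = "hazard"`) or a
#'   `surv_curves` object (`mode = "survival"`).
#' @param test A [survival_dataset()].
#' @param mode `"hazard"` or `"survival"`.
#' @return The C-index in `[0, 1]`.
#' @export
c_index <- function(scores, test, mode = c("hazard", "survival")) {
  mode <- match.arg(mode)
  pairs <- comparable_pairs(test)
  if (nrow(pairs) == 0L) stop("no comparable pairs in the test set")
  if (mode == "survival") {
    stopifnot(inherits(scores, "surv_curves"))
    ev_times <- test$times[test$events == 1]
    t_ref <- stats::median(ev_times)
    pos <- max(1L, findInterval(t_ref, scores$eval_times))
    # higher predicted survival at the reference time = lower risk
    risk <- -scores$surv[, pos]
  } else {
    risk <- as.numeric(scores)
    stopifnot(length(risk) == n_subjects(test))
  }
  r_i <- risk[pairs[, 1L]]
  r_j <- risk[pairs[, 2L]]
  conc <- sum(r_i > r_j) + 0.5 * sum(r_i == r_j)
  conc / nrow(pairs)
}

#' Integrated absolute and squared error against the Kaplan-Meier reference
#'
#' Compares the cohort-average (marginal) predicted survival curve to the
#' Kaplan-Meier estimate on the test set, both evaluated on zero plus the
#' distinct event times, via trapezoidal integration over `[0, max(t_i)]`:
#' \eqn{IAE = \int |S - \hat S| dt}, \eqn{ISE = \int (S - \hat S)^2 dt}.
#' Units follow the time unit of the data (IAE) and its square (ISE is on
#' the same time scale since the integrand is dimensionless).
#'
#' @param surv A `surv_curves` object for the test subjects.
#' @param test A [survival_dataset()].
#' @return A list with `iae` and `ise`.
#' @export
iae_ise <- function(surv, test) {
  ev_times <- sort(unique(test$times[test$events == 1]))
  if (length(ev_times) < 2L) stop("need at least 2 distinct event times")
  grid <- c(0, ev_times)
  km <- survival::survfit(survival::Surv(test$times, test$events) ~ 1,
                          se.fit = FALSE)
  S_ref <- step_eval(km$time, km$surv, grid, init = 1)
  marginal <- colMeans(surv$surv)
  pos <- findInterval(grid, surv$eval_times)
  S_hat <- ifelse(pos > 0, marginal[pmax(pos, 1L)], 1)
  list(iae = trapezoid(grid, abs(S_ref - S_hat)),
       ise = trapezoid(grid, (S_ref - S_hat)^2))
}

#' Metric report for one selector/predictor/dataset cell
#'
#' Convenience wrapper computing IBS, C-index, IAE and ISE in one pass.
#'
#' @param surv A `surv_curves` for the test subjects.
#' @param test A [survival_dataset()].
#' @param risk Optional per-subject risk scores for the hazard-mode C-index;
#'   if `NULL` the survival-mode C-index is used.
#' @return A list of class `metric_report` with `ibs`, `c_index`, `iae`,
#'   `ise`, `n_test`, `time_grid`.
#' @export
metric_report <- function(surv, test, risk = NULL) {
  G <- reverse_km(test)
  ibs <- integrated_brier(surv, test, G)
  ci <- if (is.null(risk)) c_index(surv, test, mode = "survival")
        else c_index(risk, test, mode = "hazard")
  err <- iae_ise(surv, test)
  structure(list(ibs = ibs, c_index = ci, iae = err$iae, ise = err$ise,
                 n_test = n_subjects(test), time_grid = surv$eval_times),
            class = "metric_report")
}
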