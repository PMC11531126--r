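# Independent brute-force oracles used to validate the production code on
# tiny instances. These deliberately share no code with the package: risk
# sets are enumerated explicitly, pairs by double loops.

# Random small survival dataset; distinct times unless ties requested.
rand_surv <- function(n, p, seed, tie_prob = 0, min_events = 1) {
  set.seed(seed)
  repeat {
    times <- round(stats::rexp(n) + 0.05, 3)
    if (tie_prob > 0) {
      dup <- stats::runif(n) < tie_prob
      if (any(dup) && n > 1) times[dup] <- sample(times, sum(dup), TRUE)
    } else {
      times <- times + seq_len(n) * 1e-4  # force distinct
    }
    events <- stats::rbinom(n, 1, 0.7)
    if (sum(events) >= min_events) break
  }
  X <- matrix(stats::rnorm(n * p), n, p)
  survival_dataset(times, events, X)
}

# Negative mean log partial likelihood by explicit risk-set enumeration,
# Breslow tie handling (tied events share the full risk-set denominator).
brute_neg_log_pl <- function(beta, data) {
  eta <- drop(data$covariates %*% beta)
  total <- 0
  for (i in seq_along(data$times)) {
    if (data$events[i] != 1) next
    risk <- which(data$times >= data$times[i])
    total <- total + eta[i] - log(sum(exp(eta[risk])))
  }
  -total / length(data$times)
}

# Breslow cumulative baseline hazard by direct summation.
brute_breslow <- function(beta, data) {
  eta <- drop(data$covariates %*% beta)
  ev <- sort(unique(data$times[data$events == 1]))
  H <- numeric(length(ev))
  acc <- 0
  for (k in seq_along(ev)) {
    d_k <- sum(data$times == ev[k] & data$events == 1)
    risk <- which(data$times >= ev[k])
    acc <- acc + d_k / sum(exp(eta[risk]))
    H[k] <- acc
  }
  list(times = ev, cumhaz = H)
}

# Martingale residuals by direct summation.
brute_martingale <- function(beta, data) {
  eta <- drop(data$covariates %*% beta)
  bl <- brute_breslow(beta, data)
  H_at <- function(t) {
    if (!length(bl$times) || t < bl$times[1]) return(0)
    bl$cumhaz[max(which(bl$times <= t))]
  }
  data$events - vapply(seq_along(data$times),
                       function(i) H_at(data$times[i]) * exp(eta[i]),
                       numeric(1))
}

# Comparable pairs by double loop under the stated rule.
brute_pairs <- function(data) {
  n <- length(data$times)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ti <- data$times[i]; tj <- data$times[j]
      if (data$events[i] == 1 &&
          (ti < tj || (ti == tj && data$events[j] == 0))) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# C-index by double loop (hazard mode, ties count 1/2).
brute_cindex <- function(risk, data) {
  pr <- brute_pairs(data)
  if (nrow(pr) == 0) stop("no comparable pairs")
  conc <- 0
  for (k in seq_len(nrow(pr))) {
    ri <- risk[pr[k, 1]]; rj <- risk[pr[k, 2]]
    conc <- conc + if (ri > rj) 1 else if (ri == rj) 0.5 else 0
  }
  conc / nrow(pr)
}

# Standardized log-rank statistic |W|/sqrt(V) for a fixed binary split.
brute_logrank <- function(times, events, in_left) {
  ev <- sort(unique(times[events == 1]))
  W <- 0; V <- 0
  for (t_k in ev) {
    at_risk <- times >= t_k
    Y <- sum(at_risk); Y1 <- sum(at_risk & in_left)
    d <- sum(events == 1 & times == t_k)
    d1 <- sum(events == 1 & times == t_k & in_left)
    W <- W + d1 - Y1 * d / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 1e-12) return(NA_real_)
  abs(W) / sqrt(V)
}

# Best log-rank split over all features and midpoint thresholds; requires
# both children to contain at least one event.
brute_best_split <- function(data) {
  best <- list(stat = -Inf, feature = NA, value = NA)
  for (j in seq_len(ncol(data$covariates))) {
    v <- sort(unique(data$covariates[, j]))
    if (length(v) < 2) next
    for (k in seq_len(length(v) - 1)) {
      thr <- (v[k] + v[k + 1]) / 2
      left <- data$covariates[, j] <= thr
      if (sum(data$events[left]) < 1 || sum(data$events[!left]) < 1) next
      s <- brute_logrank(data$times, data$events, left)
      if (!is.na(s) && s > best$stat) {
        best <- list(stat = s, feature = j, value = thr)
      }
    }
  }
  best
}

# Boosting j*: index minimizing the residual sum of squares of the
# univariate least-squares fit to u, on standardized columns.
brute_boost_jstar <- function(Xs, u) {
  rss <- vapply(seq_len(ncol(Xs)), function(j) {
    ss <- sum(Xs[, j]^2)
    if (ss <= 0) return(Inf)
    b <- sum(Xs[, j] * u) / ss
    sum((u - Xs[, j] * b)^2)
  }, numeric(1))
  which.min(rss)
}

# Population-sd column standardization, independent of the package helper.
std_cols <- function(X) {
  Xc <- sweep(X, 2, colMeans(X), "-")
  s <- sqrt(colSums(Xc^2) / nrow(X))
  s[s < .Machine$double.eps] <- 1
  sweep(Xc, 2, s, "/")
}

# Quick simulated recovery design shared across selector tests.
recovery_sim <- function(seed, n = 300, p = 50, k = 5, beta = 1.5,
                         censor = 0.4) {
  simulate_dataset(simulation_config(n = n, p = p, n_informative = k,
                                     beta_magnitude = beta,
                                     censor_rate = censor, seed = seed))
}
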