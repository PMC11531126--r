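# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never clobbers user RNG streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Column standardization with population (1/n) variance, the convention of
# penalized-regression solvers. Constant columns get scale 1 (coefficient
# stays 0 anyway because the centered column is identically 0).
standardize_columns <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  scale <- sqrt(colSums(Xc^2) / n)
  constant <- scale < .Machine$double.eps
  scale[constant] <- 1
  list(X = sweep(Xc, 2L, scale, "/"), center = center, scale = scale,
       constant = constant)
}

# Fold assignment stratified on the event indicator. Guarantees (by refolding
# up to `max_tries` with perturbed seeds) that every fold's complement keeps
# at least one event.
make_folds <- function(events, n_folds, seed, max_tries = 10L) {
  n <- length(events)
  for (try in seq_len(max_tries)) {
    folds <- with_seed(seed + (try - 1L), {
      f <- integer(n)
      for (g in c(0, 1)) {
        idx <- which(events == g)
        if (length(idx)) {
          f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
        }
      }
      f
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      sum(events[folds != k]) >= 1 && sum(folds == k) >= 1
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build ", n_folds, "-fold partition with events in every ",
       "training part after ", max_tries, " attempts")
}

# Right-continuous step-function evaluation: value of the step function with
# jumps at `times` (sorted) and cumulative values `values` at query points.
# Value before the first jump is `init`.
step_eval <- function(times, values, at, init = 0) {
  idx <- findInterval(at, times)
  out <- rep(init, length(at))
  pos <- idx > 0L
  out[pos] <- values[idx[pos]]
  out
}
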