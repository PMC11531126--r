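# Random survival forest: bootstrap trees with log-rank splitting (grown in
# C++), Nelson-Aalen leaf cumulative hazards on a common event-time grid,
# ensemble CHF prediction, out-of-bag error, minimal-depth statistics, and
# the two-mode variable selector (minimal depth for p/n < 10, variable
# hunting otherwise).

#' Random survival forest configuration
#'
#' @param B Number of trees (default 300).
#' @param mtry Features tried per split; defaults to `ceiling(sqrt(p))`.
#' @param nodesize Minimum number of events a node must hold to attempt a
#'   split (default 15); additionally at least 3 distinct event times are
#'   required and every child must receive at least one event.
#' @param seed Integer seed driving bootstraps, feature sampling and split
#'   tie-breaks.
#' @param vh_repeats Variable-hunting repetitions (default 50).
#' @param vh_B,vh_model_B Tree counts for the variable-hunting forests and
#'   the nested-model importance forests.
#' @return A list of class `rsf_config`.
#' @export
rsf_config <- function(B = 300L, mtry = NULL, nodesize = 15L, seed = 1L,
                       vh_repeats = 50L, vh_B = 50L, vh_model_B = 25L) {
  stopifnot(B >= 1, nodesize >= 2)
  structure(list(B = as.integer(B), mtry = mtry,
                 nodesize = as.integer(nodesize), seed = as.integer(seed),
                 vh_repeats = as.integer(vh_repeats),
                 vh_B = as.integer(vh_B),
                 vh_model_B = as.integer(vh_model_B)),
            class = "rsf_config")
}

# Nelson-Aalen cumulative hazard of (times, events) evaluated on `grid`.
nelson_aalen <- function(times, events, grid) {
  ord <- order(times)
  tt <- times[ord]; ee <- events[ord]
  ev_t <- tt[ee == 1]
  if (length(ev_t) == 0L) return(numeric(length(grid)))
  uniq <- unique(ev_t)
  d <- tabulate(match(ev_t, uniq), nbins = length(uniq))
  at_risk <- length(tt) - findInterval(uniq, tt, left.open = TRUE)
  H <- cumsum(d / at_risk)
  step_eval(uniq, H, grid)
}

#' Grow a random survival forest
#'
#' Per tree: bootstrap `n` rows with replacement, then split recursively,
#' maximizing the standardized log-rank statistic over `mtry` randomly drawn
#' features and all midpoint cut points, until a node holds fewer than
#' `nodesize` events, fewer than 3 distinct event times, or no admissible
#' split (each child must receive at least one event). Leaf cumulative
#' hazards are Nelson-Aalen estimates on the in-leaf bootstrap rows,
#' tabulated on the common grid of training event times.
#'
#' @param data A [survival_dataset()].
#' @param B,mtry,nodesize,seed See [rsf_config()].
#' @return An object of class `surv_forest`.
#' @export
grow_forest <- function(data, B = 300L, mtry = NULL, nodesize = 15L,
                        seed = 1L) {
  n <- n_subjects(data); p <- n_features(data)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (mtry > p) stop("mtry (", mtry, ") exceeds the number of features (",
                     p, ")")
  stopifnot(B >= 1, mtry >= 1, nodesize >= 2)
  grid <- sort(unique(data$times[data$events == 1]))
  X <- data$covariates
  with_seed(seed, {
    trees <- vector("list", B)
    inbag <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      tree <- grow_tree_cpp(X, data$times, data$events, idx - 1L,
                            as.integer(mtry), as.integer(nodesize), 3L)
      leaf_ids <- which(tree$feature < 0L)
      chf <- matrix(0, length(leaf_ids), length(grid))
      for (li in seq_along(leaf_ids)) {
        rows <- tree$leaf_rows[[leaf_ids[li]]] + 1L
        chf[li, ] <- nelson_aalen(data$times[rows], data$events[rows], grid)
      }
      trees[[b]] <- list(feature = tree$feature, value = tree$value,
                         left = tree$left, right = tree$right,
                         depth = tree$depth,
                         leaf_ids = leaf_ids, leaf_chf = chf)
      inbag[[b]] <- idx
    }
    structure(list(trees = trees, bootstrap_indices = inbag, grid = grid,
                   mtry = as.integer(mtry), nodesize = as.integer(nodesize),
                   B = as.integer(B), seed = as.integer(seed),
                   feature_names = colnames(X), n_train = n),
              class = "surv_forest")
  })
}

#' @export
print.surv_forest <- function(x, ...) {
  cat(sprintf("<surv_forest> B = %d trees, mtry = %d, nodesize = %d events, p = %d\n",
              x$B, x$mtry, x$nodesize, length(x$feature_names)))
  invisible(x)
}

# CHF of a single tree for each row of Xnew, on the forest grid.
tree_chf <- function(tree, Xnew) {
  leaf <- predict_leaf_cpp(tree$feature, tree$value, tree$left, tree$right,
                           Xnew) + 1L
  tree$leaf_chf[match(leaf, tree$leaf_ids), , drop = FALSE]
}

#' Ensemble cumulative hazard and survival prediction
#'
#' Drops each new row down every tree, averages the leaf Nelson-Aalen
#' cumulative hazards pointwise over trees, and converts to survival via
#' \eqn{S(t) = \exp(-CHF(t))}.
#'
#' @param forest A `surv_forest`.
#' @param X_new Numeric matrix of new covariate rows (training columns).
#' @param eval_times Non-negative sorted evaluation grid.
#' @return A `surv_curves` object; the averaged CHF matrix (rows = subjects)
#'   is attached as attribute `chf`.
#' @export
ensemble_chf <- function(forest, X_new, eval_times) {
  X_new <- as.matrix(X_new)
  stopifnot(ncol(X_new) == length(forest$feature_names))
  check_eval_times(eval_times)
  acc <- matrix(0, nrow(X_new), length(forest$grid))
  for (tree in forest$trees) acc <- acc + tree_chf(tree, X_new)
  chf_grid <- acc / forest$B
  # right-continuous step lookup from the training grid onto eval_times
  pos <- findInterval(eval_times, forest$grid)
  chf <- matrix(0, nrow(X_new), length(eval_times))
  nonzero <- pos > 0L
  if (any(nonzero)) chf[, nonzero] <- chf_grid[, pos[nonzero], drop = FALSE]
  out <- surv_curves(eval_times, pmin(pmax(exp(-chf), 0), 1))
  attr(out, "chf") <- chf
  out
}

# Ensemble mortality (sum of CHF over the training event-time grid), the
# forest's scalar risk score.
forest_mortality <- function(chf_grid) rowSums(chf_grid)

#' Out-of-bag prediction error of a survival forest
#'
#' For each training row the ensemble CHF is averaged over the trees in
#' which the row was out-of-bag; its mortality (CHF summed over the training
#' event-time grid) is the risk score, and the error is one minus the
#' C-index of those scores. Rows that are in-bag in every tree are excluded
#' with a warning.
#'
#' @param forest A `surv_forest`.
#' @param data The training [survival_dataset()].
#' @return The OOB error in `[0, 1]`.
#' @export
oob_error <- function(forest, data) {
  n <- n_subjects(data)
  acc <- matrix(0, n, length(forest$grid))
  cnt <- integer(n)
  for (b in seq_len(forest$B)) {
    oob <- setdiff(seq_len(n), forest$bootstrap_indices[[b]])
    if (length(oob) == 0L) next
    acc[oob, ] <- acc[oob, , drop = FALSE] +
      tree_chf(forest$trees[[b]], data$covariates[oob, , drop = FALSE])
    cnt[oob] <- cnt[oob] + 1L
  }
  covered <- cnt > 0L
  if (!any(covered)) stop("no row is out-of-bag in any tree; increase B")
  if (any(!covered)) {
    warning(sum(!covered), " row(s) in-bag in every tree excluded from the ",
            "OOB error")
  }
  chf <- acc[covered, , drop = FALSE] / cnt[covered]
  risk <- forest_mortality(chf)
  sub <- subset_dataset(data, which(covered))
  1 - c_index(risk, sub, mode = "hazard")
}

#' Mean minimal depth per feature
#'
#' Within each tree a feature's minimal depth is the depth of the shallowest
#' node split on it; features unused in a tree are assigned that tree's
#' maximum depth plus one. The returned value is the mean across trees;
#' smaller means more predictive.
#'
#' @param forest A `surv_forest`.
#' @return Named numeric vector of mean minimal depths.
#' @export
minimal_depth <- function(forest) {
  p <- length(forest$feature_names)
  total <- numeric(p)
  for (tree in forest$trees) {
    max_depth <- max(tree$depth)
    md <- rep(max_depth + 1, p)
    internal <- tree$feature >= 0L
    if (any(internal)) {
      f <- tree$feature[internal] + 1L
      d <- tree$depth[internal]
      for (k in seq_along(f)) md[f[k]] <- min(md[f[k]], d[k])
    }
    total <- total + md
  }
  stats::setNames(total / forest$B, forest$feature_names)
}

#' Random survival forest variable selection
#'
#' Two modes following the dimensionality rule: with `p/n < 10` features are
#' ranked by mean minimal depth and those below the forest-wide mean depth
#' are kept; with `p/n >= 10` variable hunting is used -- repeated
#' subsampled forests grow a nested model in minimal-depth order until the
#' joint out-of-bag importance stabilizes, and features appearing in at
#' least half of the repetitions are kept.
#'
#' @param data A [survival_dataset()].
#' @param config An [rsf_config()].
#' @return A [feature_set()] with method `"rsf_vs"`; `tuning$mode` records
#'   which branch ran.
#' @export
rsf_select <- function(data, config = rsf_config()) {
  n <- n_subjects(data); p <- n_features(data)
  if (p / n < 10) {
    forest <- grow_forest(data, B = config$B, mtry = config$mtry,
                          nodesize = config$nodesize, seed = config$seed)
    md <- minimal_depth(forest)
    keep <- names(md)[md < mean(md)]
    if (all(vapply(forest$trees, function(t) all(t$feature < 0L),
                   logical(1)))) {
      warning("forest grew no splits; returning empty selection")
      keep <- character(0)
    }
    feature_set(keep, method = "rsf_vs",
                tuning = list(mode = "minimal_depth", B = config$B,
                              threshold = mean(md)),
                scores = -md[keep], all_scores = -md)
  } else {
    rsf_variable_hunting(data, config)
  }
}

# Variable-hunting branch: operationalizes "repeat, grow the model in
# minimal-depth order until joint VIMP stabilizes, keep frequent features".
rsf_variable_hunting <- function(data, config) {
  n <- n_subjects(data); p <- n_features(data)
  sel_count <- stats::setNames(integer(p), colnames(data$covariates))
  n_rep <- config$vh_repeats
  for (r in seq_len(n_rep)) {
    rep_seed <- config$seed + r
    picks <- with_seed(rep_seed, {
      list(rows = sort(sample.int(n, max(2L, floor(0.8 * n)))),
           feats = sort(sample.int(p, min(p, max(2L, n)))))
    })
    sub <- subset_dataset(data, picks$rows,
                          colnames(data$covariates)[picks$feats])
    if (sum(sub$events) < 2L) next
    forest <- grow_forest(sub, B = config$vh_B, nodesize = config$nodesize,
                          seed = rep_seed)
    md <- minimal_depth(forest)
    ord <- names(sort(md))
    cap <- max(1L, min(length(ord), floor(n / 2)))
    n_init <- max(1L, sum(md < mean(md)))
    model <- ord[seq_len(min(n_init, cap))]
    vimp_path <- joint_vimp(sub, model, config, rep_seed)
    k <- length(model)
    while (k < cap) {
      k <- k + 1L
      model <- ord[seq_len(k)]
      vimp_path <- c(vimp_path, joint_vimp(sub, model, config, rep_seed))
      if (length(vimp_path) >= 4L) {
        recent <- utils::tail(vimp_path, 4L)
        rel <- abs(diff(recent)) / pmax(abs(recent[-length(recent)]), 1e-8)
        if (all(rel < 1e-3)) break
      }
    }
    sel_count[model] <- sel_count[model] + 1L
  }
  keep <- names(sel_count)[sel_count >= n_rep / 2]
  if (length(keep) == 0L) {
    warning("variable hunting selected no features")
  }
  feature_set(keep, method = "rsf_vs",
              tuning = list(mode = "variable_hunting",
                            repeats = n_rep, B = config$vh_B),
              scores = sel_count[keep] / n_rep,
              all_scores = sel_count / n_rep)
}

# Joint importance of a feature subset: 1 - OOB error of a small forest
# grown on those features alone.
joint_vimp <- function(data, features, config, seed) {
  sub <- subset_dataset(data, features = features)
  forest <- grow_forest(sub, B = config$vh_model_B,
                        nodesize = config$nodesize, seed = seed)
  err <- tryCatch(oob_error(forest, sub), error = function(e) 0.5)
  1 - err
}

#' Dump a forest as JSON lines (diagnostics)
#'
#' One JSON object per tree with the node table (split feature by name,
#' threshold, child indices, depth). Intended for inspection, not round
#' tripping.
#'
#' @param forest A `surv_forest`.
#' @param path Output path for the JSON-lines dump.
#' @export
forest_to_jsonl <- function(forest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in seq_along(forest$trees)) {
    tree <- forest$trees[[b]]
    feat <- ifelse(tree$feature >= 0L,
                   forest$feature_names[tree$feature + 1L], NA)
    obj <- list(tree = b,
                nodes = list(feature = feat, value = tree$value,
                             left = tree$left, right = tree$right,
                             depth = tree$depth))
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, na = "null")),
               con)
  }
  invisible(path)
}
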