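# Majority-vote hybrid feature selection: run the four base selectors
# (lasso, SCAD, boosting, random survival forest) and keep the features
# chosen by at least `threshold` of them (default 3 of 4).

#' Construct a feature set
#'
#' A named subset of covariates with provenance: which selector produced it,
#' the tuning values used, and per-feature scores.
#'
#' @param features Character vector of selected feature names (no
#'   duplicates).
#' @param method Selector label.
#' @param tuning Named list of tuning-parameter values.
#' @param scores Optional named numeric scores for the selected features.
#' @param all_scores Optional named numeric ranking over all candidate
#'   features (used by the benchmark layer's empty-selection fallback).
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(features, method = "unknown", tuning = list(),
                        scores = NULL, all_scores = NULL) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicate features in feature set")
  structure(list(features = features, method = method, tuning = tuning,
                 scores = scores, all_scores = all_scores),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set method='%s'> %d feature(s): %s\n", x$method,
              length(x$features),
              paste(utils::head(x$features, 10), collapse = ", ")))
  invisible(x)
}

#' Serialize a feature set to JSON
#'
#' @param fs A [feature_set()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
feature_set_to_json <- function(fs, path = NULL) {
  obj <- list(method = fs$method, tuning = fs$tuning,
              features = lapply(fs$features, function(f) {
                list(name = f,
                     score = if (!is.null(fs$scores)) unname(fs$scores[f])
                             else NULL)
              }))
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else { jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
         invisible(path) }
}

#' Run all four base selectors
#'
#' Applies LASSO-Cox, RSF variable selection, SCAD-Cox and CoxBoost to the
#' same dataset. If any selector errors the hybrid aborts with a message
#' naming it: a majority vote over fewer than four sets would silently
#' change the rule's semantics.
#'
#' @param data A [survival_dataset()].
#' @param configs Named list of per-selector settings: `lasso` and `scad`
#'   are [penalty_config()]s, `coxboost` a list of arguments for
#'   [coxboost_select()], `rsf` an [rsf_config()].
#' @return A named list of four [feature_set()]s
#'   (`lasso`, `rsf_vs`, `scad`, `coxboost`).
#' @export
run_all_selectors <- function(data, configs = default_selector_configs()) {
  runners <- list(
    lasso = function() lasso_select(data, configs$lasso),
    rsf_vs = function() rsf_select(data, configs$rsf),
    scad = function() scad_select(data, configs$scad),
    coxboost = function() do.call(coxboost_select,
                                  c(list(data = data), configs$coxboost)))
  out <- vector("list", length(runners))
  names(out) <- names(runners)
  for (nm in names(runners)) {
    out[[nm]] <- tryCatch(runners[[nm]](), error = function(e) e)
    if (inherits(out[[nm]], "error")) {
      stop("base selector '", nm, "' failed: ",
           conditionMessage(out[[nm]]))
    }
  }
  out
}

#' Default per-selector configurations
#'
#' @param seed Base seed shared by the seeded selectors.
#' @param rsf_B Number of survival trees for the forest selector.
#' @return A named list suitable for [run_all_selectors()].
#' @export
default_selector_configs <- function(seed = 1L, rsf_B = 300L) {
  list(lasso = penalty_config("lasso", seed = seed),
       scad = penalty_config("scad", seed = seed),
       coxboost = list(nu = 0.1, m_grid = 0:200, n_folds = 10L, seed = seed),
       rsf = rsf_config(B = rsf_B, seed = seed))
}

#' Count selector votes per feature
#'
#' Tallies, over the union of the supplied feature sets, how many sets
#' contain each feature. Features selected nowhere do not appear.
#'
#' @param sets A list of 2--4 [feature_set()]s.
#' @param threshold Vote threshold recorded in the tally (default 3).
#' @return An object of class `vote_tally`: `counts` (named integer vector,
#'   descending), `source_sets`, `threshold`.
#' @export
count_votes <- function(sets, threshold = 3L) {
  stopifnot(length(sets) >= 2L, length(sets) <= 4L,
            all(vapply(sets, inherits, logical(1), "feature_set")))
  all_feats <- unlist(lapply(sets, `[[`, "features"), use.names = FALSE)
  if (length(all_feats) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    counts <- table(all_feats)
    counts <- sort(stats::setNames(as.integer(counts), names(counts)),
                   decreasing = TRUE)
  }
  structure(list(counts = counts, source_sets = sets,
                 threshold = as.integer(threshold)),
            class = "vote_tally")
}

#' Majority-vote feature selection
#'
#' Keeps the features appearing in at least `threshold` of the tallied
#' sets (the proposed rule: at least three of the four base selectors),
#' ordered by descending vote count then name. An empty result is returned
#' as such, with a prominent warning; downstream consumers decide the
#' fallback.
#'
#' @param tally A `vote_tally` from [count_votes()].
#' @param threshold Optional override of the tally's threshold.
#' @return A [feature_set()] with method `"proposed"`; scores are the vote
#'   counts.
#' @export
hybrid_select <- function(tally, threshold = tally$threshold) {
  stopifnot(inherits(tally, "vote_tally"),
            threshold >= 1L, threshold <= length(tally$source_sets))
  counts <- tally$counts
  keep <- counts[counts >= threshold]
  if (length(keep)) {
    ord <- order(-keep, names(keep))
    keep <- keep[ord]
  } else {
    warning("majority vote selected no features (threshold ", threshold,
            " of ", length(tally$source_sets), " sets)")
  }
  all_counts <- stats::setNames(as.numeric(counts), names(counts))
  feature_set(names(keep), method = "proposed",
              tuning = list(threshold = as.integer(threshold),
                            n_sets = length(tally$source_sets)),
              scores = stats::setNames(as.numeric(keep), names(keep)),
              all_scores = all_counts)
}

#' Run the full hybrid selection pipeline
#'
#' [run_all_selectors()], [count_votes()] and [hybrid_select()] in one call.
#'
#' @inheritParams run_all_selectors
#' @param threshold Vote threshold (default 3).
#' @return A list with `selection` (the final [feature_set()]), `tally`, and
#'   `base_sets`.
#' @export
hybrid_pipeline <- function(data, configs = default_selector_configs(),
                            threshold = 3L) {
  sets <- run_all_selectors(data, configs)
  tally <- count_votes(sets, threshold)
  list(selection = hybrid_select(tally), tally = tally, base_sets = sets)
}

#' Serialize a hybrid-selection result to JSON
#'
#' Emits the four base sets, the vote tally, the final selection and
#' per-feature provenance (which selectors chose each feature).
#'
#' @param pipeline Result of [hybrid_pipeline()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
hybrid_report_json <- function(pipeline, path = NULL) {
  sets <- pipeline$base_sets
  counts <- pipeline$tally$counts
  provenance <- lapply(names(counts), function(f) {
    list(feature = f, count = unname(counts[[f]]),
         selected_by = names(sets)[vapply(sets, function(fs) {
           f %in% fs$features
         }, logical(1))])
  })
  obj <- list(
    base_sets = lapply(sets, function(fs) {
      list(method = fs$method, features = fs$features, tuning = fs$tuning)
    }),
    threshold = pipeline$tally$threshold,
    final = pipeline$selection$features,
    provenance = provenance)
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else { jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
         invisible(path) }
}
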