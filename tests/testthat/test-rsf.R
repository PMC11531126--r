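test_that("root splits match brute-force log-rank search on tiny data", {
  for (s in 1:25) {
    d <- rand_surv(sample(8:10, 1), 2, seed = 800 + s, min_events = 6)
    # full feature search, no bootstrap randomness in the comparison:
    # grow a stump on the identity bootstrap
    n <- length(d$times)
    set.seed(s)
    tree <- hfsurv:::grow_tree_cpp(d$covariates, d$times, d$events,
                                   seq_len(n) - 1L, 2L, 2L, 2L)
    oracle <- brute_best_split(d)
    if (is.na(oracle$feature)) {
      expect_true(all(tree$feature < 0L))  # no admissible split anywhere
    } else {
      chosen <- brute_logrank(
        d$times, d$events,
        d$covariates[, tree$feature[1] + 1L] <= tree$value[1])
      expect_equal(chosen, oracle$stat, tolerance = 1e-10)
    }
  }
})

test_that("a perfectly separating covariate is always the root split", {
  # early events for x < 0, late events for x > 0, all uncensored
  x <- c(rep(-1, 20) + rnorm(20, sd = 0.05), rep(1, 20) + rnorm(20, sd = 0.05))
  times <- c(runif(20, 0.1, 1), runif(20, 5, 6))
  d <- survival_dataset(times, rep(1, 40), cbind(x, noise = rnorm(40)))
  f <- grow_forest(d, B = 10, mtry = 2, nodesize = 5, seed = 3)
  roots <- vapply(f$trees, function(t) t$feature[1] + 1L, integer(1))
  expect_true(all(roots == 1L))
})

test_that("forests are reproducible under a seed", {
  d <- recovery_sim(12, n = 100, p = 8, k = 2, beta = 1.2,
                    censor = 0.3)$data
  f1 <- grow_forest(d, B = 20, seed = 7)
  f2 <- grow_forest(d, B = 20, seed = 7)
  expect_identical(f1$bootstrap_indices, f2$bootstrap_indices)
  expect_identical(lapply(f1$trees, `[[`, "feature"),
                   lapply(f2$trees, `[[`, "feature"))
  expect_identical(lapply(f1$trees, `[[`, "value"),
                   lapply(f2$trees, `[[`, "value"))
  f3 <- grow_forest(d, B = 20, seed = 8)
  expect_false(identical(lapply(f1$trees, `[[`, "value"),
                         lapply(f3$trees, `[[`, "value")))
  expect_error(grow_forest(d, B = 5, mtry = 50), "exceeds")
})

test_that("bootstrap out-of-bag fractions concentrate near 1/e", {
  d <- recovery_sim(13, n = 150, p = 4, k = 1, beta = 1, censor = 0.3)$data
  f <- grow_forest(d, B = 60, seed = 1)
  oob_frac <- vapply(f$bootstrap_indices, function(idx) {
    1 - length(unique(idx)) / 150
  }, numeric(1))
  expect_lt(abs(mean(oob_frac) - exp(-1)), 0.03)
})

test_that("ensemble CHF averages trees and yields monotone survival", {
  d <- recovery_sim(14, n = 80, p = 3, k = 1, beta = 1.2,
                    censor = 0.3)$data
  f1 <- grow_forest(d, B = 1, seed = 5)
  grid <- c(0, f1$grid)
  sc <- ensemble_chf(f1, d$covariates[1:4, ], grid)
  chf1 <- hfsurv:::tree_chf(f1$trees[[1]], d$covariates[1:4, ])
  expect_equal(attr(sc, "chf")[, -1], chf1[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # t = 0: no accrued hazard, S = 1
  expect_equal(attr(sc, "chf")[, 1], rep(0, 4))
  expect_equal(sc$surv[, 1], rep(1, 4))

  f <- grow_forest(d, B = 25, seed = 5)
  sc2 <- ensemble_chf(f, d$covariates, grid)
  expect_true(all(sc2$surv >= 0 & sc2$surv <= 1))
  expect_true(all(apply(attr(sc2, "chf"), 1,
                        function(r) all(diff(r) >= -1e-12))))

  # averaging two leaf CHFs H and 3H gives 2H: averaged CHF equals the
  # mean of the per-tree CHFs by construction
  two <- grow_forest(d, B = 2, seed = 9)
  sc3 <- ensemble_chf(two, d$covariates[1:3, ], grid)
  manual <- (hfsurv:::tree_chf(two$trees[[1]], d$covariates[1:3, ]) +
               hfsurv:::tree_chf(two$trees[[2]], d$covariates[1:3, ])) / 2
  expect_equal(attr(sc3, "chf")[, -1], manual, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rank-preserving covariate transforms leave predictions unchanged", {
  d <- recovery_sim(15, n = 100, p = 3, k = 1, beta = 1.5,
                    censor = 0.3)$data
  # strictly monotone transform of every column
  Xt <- exp(d$covariates)
  dt <- survival_dataset(d$times, d$events, Xt)
  grid <- sort(unique(d$times))
  f1 <- grow_forest(d, B = 15, seed = 21)
  f2 <- grow_forest(dt, B = 15, seed = 21)
  s1 <- ensemble_chf(f1, d$covariates, grid)
  s2 <- ensemble_chf(f2, Xt, grid)
  expect_equal(s1$surv, s2$surv, tolerance = 1e-12)
})

test_that("OOB error separates informative from null forests", {
  errs <- vapply(1:3, function(s) {
    sim <- simulate_dataset(simulation_config(n = 200, p = 1,
                                              n_informative = 1,
                                              beta_magnitude = 2,
                                              censor_rate = 0.2, seed = s))
    f <- grow_forest(sim$data, B = 100, seed = s)
    oob_error(f, sim$data)
  }, numeric(1))
  expect_true(all(errs >= 0 & errs <= 1))
  expect_lt(mean(errs), 0.25)

  null_errs <- vapply(1:5, function(s) {
    sim <- simulate_dataset(simulation_config(n = 150, p = 5,
                                              n_informative = 0,
                                              beta_magnitude = 0,
                                              censor_rate = 0.3, seed = s))
    f <- grow_forest(sim$data, B = 60, seed = s)
    oob_error(f, sim$data)
  }, numeric(1))
  expect_lt(abs(mean(null_errs) - 0.5), 0.1)
})

test_that("minimal depth ranks a dominant feature first", {
  d <- recovery_sim(16, n = 100, p = 4, k = 1, beta = 2, censor = 0.2)$data
  f <- grow_forest(d, B = 30, seed = 2)
  md <- minimal_depth(f)
  expect_named(md, colnames(d$covariates))

  # a feature splitting the root of every tree has mean minimal depth 0
  x <- c(rep(-1, 25), rep(1, 25)) + rnorm(50, sd = 0.01)
  dsep <- survival_dataset(c(runif(25, 0.1, 1), runif(25, 5, 6)),
                           rep(1, 50), cbind(x, rnorm(50)))
  fsep <- grow_forest(dsep, B = 10, mtry = 2, nodesize = 5, seed = 1)
  expect_equal(unname(minimal_depth(fsep)[1]), 0)

  # unused features receive (max depth + 1), larger than any used feature
  wins <- vapply(1:10, function(s) {
    sim <- recovery_sim(900 + s, n = 120, p = 8, k = 1, beta = 2,
                        censor = 0.3)
    f <- grow_forest(sim$data, B = 40, seed = s)
    which.min(minimal_depth(f)) == 1L
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the selector takes the documented branch by dimensionality", {
  lowdim <- recovery_sim(17, n = 100, p = 5, k = 2, beta = 1.5,
                         censor = 0.3)$data
  fs <- rsf_select(lowdim, rsf_config(B = 40, seed = 1))
  expect_identical(fs$tuning$mode, "minimal_depth")

  highdim <- simulate_dataset(simulation_config(n = 25, p = 300,
                                                n_informative = 2,
                                                beta_magnitude = 2,
                                                censor_rate = 0.2,
                                                seed = 18))$data
  # tiny VH forests leave a few rows in-bag everywhere; that warning is
  # expected at this scale
  fs2 <- suppressWarnings(
    rsf_select(highdim, rsf_config(B = 10, nodesize = 5, seed = 1,
                                   vh_repeats = 3, vh_B = 8,
                                   vh_model_B = 5)))
  expect_identical(fs2$tuning$mode, "variable_hunting")
})

test_that("minimal-depth selection recovers planted features", {
  res <- vapply(1:10, function(s) {
    sim <- recovery_sim(1000 + s, n = 200, p = 40, k = 5, beta = 1.5,
                        censor = 0.4)
    fs <- rsf_select(sim$data, rsf_config(B = 100, seed = s))
    truth <- names(sim$true_beta)[sim$true_beta != 0]
    sum(truth %in% fs$features)
  }, numeric(1))
  expect_gte(mean(res >= 3), 0.7)
})
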