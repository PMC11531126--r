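test_that("SCAD derivative reproduces its defining branches and is continuous", {
  expect_equal(scad_derivative(0.5, 1, 3.7), 1)
  expect_equal(scad_derivative(5, 1, 3.7), 0)
  expect_equal(scad_derivative(2, 1, 3.7), (3.7 - 2) / 2.7, tolerance = 1e-12)
  expect_error(scad_derivative(1, 1, a = 2), "a > 2")

  # continuity at the breakpoints lambda and a*lambda
  for (lam in c(0.3, 1, 2.5)) {
    a <- 3.7
    eps <- 1e-9
    expect_equal(scad_derivative(lam - eps, lam, a),
                 scad_derivative(lam + eps, lam, a), tolerance = 1e-6)
    expect_equal(scad_derivative(a * lam - eps, lam, a),
                 scad_derivative(a * lam + eps, lam, a), tolerance = 1e-6)
  }

  # penalty primitive is the integral of the derivative
  for (b in c(0.2, 0.9, 1.7, 3.1, 6)) {
    num <- stats::integrate(function(t) scad_derivative(t, 1, 3.7), 0, b,
                            rel.tol = 1e-10)$value
    expect_equal(hfsurv:::scad_penalty(b, 1, 3.7), num, tolerance = 1e-7)
  }
})

test_that("penalized objective reduces to its parts", {
  d <- rand_surv(15, 2, seed = 21)
  cfg <- penalty_config("lasso")
  beta <- c(1, -2)
  expect_equal(penalized_objective(beta, d, cfg, 0),
               neg_log_partial_likelihood(beta, d))
  expect_equal(penalized_objective(numeric(2), d, cfg, 0.7),
               neg_log_partial_likelihood(numeric(2), d))
  expect_equal(penalized_objective(beta, d, cfg, 0.5),
               neg_log_partial_likelihood(beta, d) + 1.5, tolerance = 1e-12)
  expect_error(penalized_objective(beta, d, cfg, -1), "non-negative")
})

test_that("quadratic coordinate solver matches closed-form soft-thresholding", {
  # 1-D quadratic: min 0.5 h (b - m)^2 + lambda |b|  ->  S(h m, lambda)/h
  for (s in 1:20) {
    set.seed(s)
    h <- runif(1, 0.5, 3); m <- rnorm(1, sd = 2); lam <- runif(1, 0, 2)
    g <- -h * m   # gradient at b = 0 of 0.5 h (b - m)^2
    sol <- hfsurv:::cd_quad_l1_cpp(matrix(h), g, 0, lam, 1, 0, 1e-14, 500L)
    closed <- sign(m) * max(abs(h * m) - lam, 0) / h
    expect_equal(drop(sol), closed, tolerance = 1e-10)
  }
})

test_that("the lasso path is sparse at lambda_max and matches Newton at 0", {
  d <- recovery_sim(31, n = 150, p = 8, k = 2, beta = 1, censor = 0.3)$data
  cfg <- penalty_config("lasso")
  std <- hfsurv:::standardize_columns(d$covariates)
  lmax <- hfsurv:::lambda_max_value(std$X, d$times, d$events)
  f_hi <- fit_penalized_cox(d, cfg, lmax * 1.000001)
  expect_equal(f_hi$n_nonzero, 0L)

  d2 <- recovery_sim(32, n = 200, p = 2, k = 1, beta = 1, censor = 0.3)$data
  f0 <- fit_penalized_cox(d2, cfg, 0)
  expect_equal(unname(f0$beta), unname(fit_cox(d2)$beta), tolerance = 1e-4)
})

test_that("sparsity grows with lambda along the path", {
  for (s in 1:5) {
    d <- recovery_sim(40 + s, n = 120, p = 15, k = 3, beta = 1,
                      censor = 0.3)$data
    cfg <- penalty_config("lasso")
    std <- hfsurv:::standardize_columns(d$covariates)
    lmax <- hfsurv:::lambda_max_value(std$X, d$times, d$events)
    grid <- hfsurv:::default_lambda_grid(lmax, n_lambda = 12)
    warm <- NULL
    nnz <- integer(length(grid))
    for (i in seq_along(grid)) {
      f <- fit_penalized_cox(d, cfg, grid[i], beta_init = warm)
      warm <- f$beta_std
      nnz[i] <- f$n_nonzero
    }
    # grid is decreasing, so nonzero count must be non-decreasing
    expect_true(all(diff(nnz) >= 0))
  }
})

test_that("penalized solutions do not exceed the objective at the origin", {
  d <- recovery_sim(55, n = 150, p = 10, k = 3, beta = 1.2,
                    censor = 0.3)$data
  std <- hfsurv:::standardize_columns(d$covariates)
  lmax <- hfsurv:::lambda_max_value(std$X, d$times, d$events)
  lam <- 0.2 * lmax
  for (kind in c("lasso", "scad")) {
    cfg <- penalty_config(kind)
    fit <- fit_penalized_cox(d, cfg, lam)
    ds <- survival_dataset(d$times, d$events, std$X)
    expect_lte(penalized_objective(fit$beta_std, ds, cfg, lam),
               penalized_objective(numeric(10), ds, cfg, lam) + 1e-10)
  }
  # SCAD/LLA must not be worse than its lasso initialization
  lasso_fit <- fit_penalized_cox(d, penalty_config("lasso"), lam)
  scad_fit <- fit_penalized_cox(d, penalty_config("scad"), lam)
  ds <- survival_dataset(d$times, d$events, std$X)
  scfg <- penalty_config("scad")
  expect_lte(penalized_objective(scad_fit$beta_std, ds, scfg, lam),
             penalized_objective(lasso_fit$beta_std, ds, scfg, lam) + 1e-8)
})

test_that("our lasso path tracks glmnet on a moderate design", {
  skip_if_not_installed("glmnet")
  d <- recovery_sim(7, n = 300, p = 50, k = 5, beta = 1.5,
                    censor = 0.4)$data
  g <- glmnet::glmnet(d$covariates,
                      survival::Surv(d$times, d$events), family = "cox",
                      standardize = TRUE)
  for (li in c(10, 25)) {
    lam <- g$lambda[li]
    ours <- fit_penalized_cox(d, penalty_config("lasso"), lam)
    ref <- as.numeric(stats::coef(g, s = lam, exact = FALSE))
    expect_lt(max(abs(ours$beta - ref)), 0.05)
    # every strong glmnet coefficient is in our support
    expect_true(all(which(abs(ref) > 0.05) %in% which(ours$beta != 0)))
  }
})

test_that("cross-validated lambda is deterministic and shrinks with more data", {
  d <- recovery_sim(61, n = 100, p = 10, k = 3, beta = 1.5,
                    censor = 0.3)$data
  cfg <- penalty_config("lasso", n_folds = 5, seed = 3)
  l1 <- select_lambda_cv(d, cfg)
  l2 <- select_lambda_cv(d, cfg)
  expect_identical(as.numeric(l1), as.numeric(l2))

  # duplicating rows 5x: more evidence, less shrinkage
  smaller <- vapply(1:5, function(s) {
    ds <- recovery_sim(70 + s, n = 80, p = 10, k = 3, beta = 1.5,
                       censor = 0.3)$data
    idx <- rep(seq_len(80), 5)
    dup <- survival_dataset(ds$times[idx], ds$events[idx],
                            ds$covariates[idx, ])
    cfg_s <- penalty_config("lasso", n_folds = 5, seed = s)
    as.numeric(select_lambda_cv(dup, cfg_s)) <
      as.numeric(select_lambda_cv(ds, cfg_s))
  }, logical(1))
  expect_gte(mean(smaller), 0.8)
})

test_that("lasso recovers planted support and stays near-empty on noise", {
  hits <- vapply(1:10, function(s) {
    sim <- recovery_sim(200 + s, n = 200, p = 30, k = 5, beta = 1.5,
                        censor = 0.4)
    fs <- lasso_select(sim$data, penalty_config("lasso", seed = s))
    truth <- names(sim$true_beta)[sim$true_beta != 0]
    sum(truth %in% fs$features)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.8)

  sizes <- vapply(1:10, function(s) {
    sim <- simulate_dataset(simulation_config(n = 120, p = 15,
                                              n_informative = 0,
                                              beta_magnitude = 0,
                                              censor_rate = 0.3, seed = s))
    length(lasso_select(sim$data,
                        penalty_config("lasso", seed = s))$features)
  }, numeric(1))
  expect_gte(mean(sizes <= 2), 0.7)
})

test_that("SCAD keeps the strong features with fewer false positives than lasso", {
  fdp <- vapply(1:8, function(s) {
    sim <- recovery_sim(300 + s, n = 200, p = 30, k = 5, beta = 1.5,
                        censor = 0.4)
    truth <- names(sim$true_beta)[sim$true_beta != 0]
    fl <- lasso_select(sim$data, penalty_config("lasso", seed = s))$features
    fscad <- scad_select(sim$data, penalty_config("scad", seed = s))$features
    c(lasso_fp = sum(!fl %in% truth), scad_fp = sum(!fscad %in% truth),
      scad_hits = sum(truth %in% fscad))
  }, numeric(3))
  expect_lte(mean(fdp["scad_fp", ]), mean(fdp["lasso_fp", ]) + 0.5)
  expect_gte(mean(fdp["scad_hits", ] >= 4), 0.8)
})
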