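test_that("estimate_theta is the exact ratio of score sums", {
  # hand evaluation: num = 1*2 + (-1)*0 + 0*1 = 2; den = 1*1 = 1
  expect_identical(estimate_theta(c(1, -1, 0), c(2, 0, 1), c(1, 0, 0)), 2)
  # proportional case: ytilde = c * vhat and d = vhat  ->  theta = c
  v <- c(0.3, -1.2, 0.5, 0.4)
  expect_equal(estimate_theta(v, 3.7 * v, v), 3.7)
  # orthogonal residuals -> zero
  expect_equal(estimate_theta(c(1, -1), c(1, 1), c(1, 0)), 1 / 1 - 1)  # = 0
  expect_error(estimate_theta(c(0, 0), c(1, 2), c(1, 1)), "zero")
})

test_that("cross-fitting partitions exactly and is seed-deterministic", {
  set.seed(99)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] + rnorm(n)
  d <- rbinom(n, 1, 0.5)
  cfg <- dml_config(n_folds = 5, learner = "linear", seed = 4)
  nf <- crossfit_nuisances(y, d, X, cfg)
  expect_equal(unname(table(nf$folds)), rep(20L, 5), ignore_attr = TRUE)
  nf2 <- crossfit_nuisances(y, d, X, cfg)
  expect_identical(nf, nf2)
  nf3 <- crossfit_nuisances(y, d, X, cfg, seed = 5)
  expect_false(identical(nf$folds, nf3$folds))
})

test_that("linear learner reproduces a realizable outcome out-of-fold", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(2 + X %*% c(1, -1, 0.5, 0))       # exactly linear, no noise
  d <- rbinom(n, 1, 0.5)                      # independent of X
  nf <- crossfit_nuisances(y, d, X, dml_config(learner = "linear", seed = 1))
  expect_equal(nf$ghat, y, tolerance = 1e-8)
  expect_lt(mean(abs(nf$mhat - mean(d))), 0.15)
  # constant treatment in training folds falls back to mean with a warning
  d0 <- c(1, rep(0, n - 1))
  expect_warning(crossfit_nuisances(y, d0, X,
                                    dml_config(learner = "linear", seed = 2)),
                 "constant treatment")
})

test_that("DML with linear learner matches the FWL oracle on a linear DGP", {
  cfg <- linear_cfg(n_cities = 100, n_years = 10, theta = 0.5, seed = 31)
  p <- generate_panel(cfg)
  X <- build_design(p, prep_config(add_squares = FALSE, fe_year = FALSE))
  fit <- dml_plr(p, design = X, cfg = lin_dml(seed = 31))
  oracle <- fwl_oracle(p$PHL, p$SCC, X)
  expect_lt(abs(fit$theta_hat - oracle), 0.01)
})

test_that("orthogonality diagnostics hold when the treatment nuisance is
           realizable", {
  # unconfounded adoption: the true propensity depends on year only, so
  # the linear learner with year dummies estimates it consistently and
  # the residual-vs-prediction correlation must vanish (n > 1000)
  cfg <- linear_cfg(n_cities = 120, n_years = 10, seed = 41,
                    confounding_strength = 0, instrument_strength = 0)
  p <- generate_panel(cfg)
  fit <- dml_plr(p, design = prep_config(add_squares = FALSE),
                 cfg = lin_dml(seed = 41))
  expect_lt(abs(fit$diagnostics$mean_vhat), 0.05)
  expect_lt(abs(fit$diagnostics$cor_vhat_mhat), 0.05)
  # confounded fit: residual mean still centered
  cfg2 <- linear_cfg(n_cities = 120, n_years = 10, seed = 42)
  fit2 <- dml_plr(generate_panel(cfg2),
                  design = prep_config(add_squares = FALSE),
                  cfg = lin_dml(seed = 42))
  expect_lt(abs(fit2$diagnostics$mean_vhat), 0.05)
})

test_that("theta invariant to outcome translation with the linear learner", {
  cfg <- linear_cfg(n_cities = 50, n_years = 8, seed = 51)
  p <- generate_panel(cfg)
  X <- build_design(p, prep_config(add_squares = FALSE, fe_year = FALSE))
  f1 <- dml_plr(p, design = X, cfg = lin_dml(seed = 3))
  p2 <- p; p2$PHL <- p2$PHL + 100
  f2 <- dml_plr(p2, design = X, cfg = lin_dml(seed = 3))
  expect_equal(f1$theta_hat, f2$theta_hat, tolerance = 1e-10)
})

test_that("result object contract: CI, t ratio, repeats, clustering options", {
  cfg <- linear_cfg(n_cities = 40, n_years = 8, seed = 61)
  p <- generate_panel(cfg)
  X <- build_design(p, prep_config(add_squares = FALSE, fe_year = FALSE))
  fit <- dml_plr(p, design = X, cfg = lin_dml(seed = 2, n_repeats = 3))
  expect_equal(fit$ci95, fit$theta_hat + c(-1.96, 1.96) * fit$se)
  expect_equal(fit$t_stat, fit$theta_hat / fit$se)
  expect_length(fit$thetas, 3)
  expect_equal(fit$theta_hat, stats::median(fit$thetas))
  # cluster-blocked folds keep whole cities together
  cfgc <- lin_dml(seed = 2, cluster_folds = TRUE)
  nf <- crossfit_nuisances(p$PHL, p$SCC, X, cfgc, clusters = p$city_id)
  per_city <- tapply(nf$folds, p$city_id, function(f) length(unique(f)))
  expect_true(all(per_city == 1))
  expect_error(dml_plr(transform(p, SCC = 0L), design = X, cfg = lin_dml()),
               "no variation")
})

test_that("gradient boosting learner runs and preserves the effect sign", {
  cfg <- linear_cfg(n_cities = 60, n_years = 8, theta = 0.5, seed = 71)
  p <- generate_panel(cfg)
  X <- build_design(p, prep_config(add_squares = FALSE, fe_year = FALSE))
  fit <- dml_plr(p, design = X,
                 cfg = dml_config(learner = "gradient_boosting",
                                  learner_params = list(nrounds = 50), seed = 7))
  expect_gt(fit$theta_hat, 0)
  expect_gt(fit$t_stat, 1.96)
})
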