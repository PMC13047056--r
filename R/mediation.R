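#' Treatment-to-mediator path (a-path)
#'
#' The a-path is the effect of the policy on the mediator, estimated by
#' the same cross-fitted partial-linear estimator with the mediator as
#' the outcome.
#'
#' @inheritParams dml_plr
#' @param mediator name of the mediator column.
#' @return a \code{dml_result} for the mediator regression.
#' @export
path_a <- function(panel, mediator, treatment = "SCC",
                   design = prep_config(), cfg = dml_config(),
                   controls = NULL) {
  dml_plr(panel, outcome = mediator, treatment = treatment,
          design = design, cfg = cfg, controls = controls)
}

# Joint two-residual regression shared by path_b and the bootstrap:
# cross-fits E[Y|X], E[D|X], E[M|X] once, then regresses the outcome
# residual on the treatment and mediator residuals jointly (no
# intercept; residuals are mean-zero by construction up to noise).
# Returns coefficients, clustered sandwich SEs and the a-path estimate
# computed from the same residual set.
joint_residual_fit <- function(y, d, m, X, cfg, clusters, seed) {
  n <- length(y)
  learner <- get_learner(cfg$learner)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fold <- make_folds(n, cfg$n_folds, clusters, cfg$cluster_folds)
  ghat <- mhat <- hhat <- numeric(n)
  for (k in seq_len(cfg$n_folds)) {
    te <- fold == k; tr <- !te
    if (!any(te)) next
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ghat[te] <- learner(y[tr], Xtr, Xte, cfg$learner_params, sub_seed)
    mhat[te] <- if (stats::var(d[tr]) == 0) mean(d[tr]) else
      learner(d[tr], Xtr, Xte, cfg$learner_params, sub_seed + 1L)
    hhat[te] <- learner(m[tr], Xtr, Xte, cfg$learner_params, sub_seed + 2L)
  }
  if (all(d %in% c(0, 1))) mhat <- pmin(pmax(mhat, 0), 1)
  yt <- y - ghat; dt <- d - mhat; mt <- m - hhat
  if (stats::sd(dt) == 0 || stats::sd(mt) == 0)
    stop("no residual variation in treatment or mediator")
  if (abs(stats::cor(dt, mt)) > 0.999)
    stop("treatment and mediator residuals are collinear")
  S <- cbind(dt = dt, mt = mt)
  A <- solve(crossprod(S))
  coefs <- drop(A %*% crossprod(S, yt))
  u <- yt - drop(S %*% coefs)
  # cluster-summed score sandwich for the two-column residual OLS
  sc <- S * u
  cl_sums <- rowsum(sc, group = clusters)
  meat <- crossprod(cl_sums)
  V <- A %*% meat %*% A
  # a-path from the same residual set: orthogonalized ratio for M on D
  a_hat <- sum(dt * mt) / sum(dt * d)
  psi_a <- dt * (mt - a_hat * d)
  var_a <- cluster_if_variance(psi_a, sum(dt * d), clusters)
  list(b_hat = coefs[["mt"]], theta_direct = coefs[["dt"]],
       se_b = sqrt(V[2, 2]), se_theta = sqrt(V[1, 1]),
       a_hat = a_hat, se_a = sqrt(var_a),
       cor_dt_mt = stats::cor(dt, mt))
}

#' Mediator-to-outcome path (b-path) with the direct effect
#'
#' Cross-fits the three nuisances E[Y|X], E[D|X], E[M|X] and regresses
#' the outcome residual jointly on the treatment and mediator residuals,
#' mirroring a mechanism regression that includes policy and mediator
#' together.  Returns the mediator coefficient (b-path) and the
#' treatment coefficient (direct effect), each with city-clustered
#' influence-function standard errors.
#'
#' @inheritParams path_a
#' @param outcome outcome column name.
#' @return list with \code{b_hat}, \code{se_b}, \code{t_b},
#'   \code{theta_direct}, \code{se_theta}, \code{t_theta}, \code{a_hat},
#'   \code{se_a} and \code{n_obs}.
#' @export
path_b <- function(panel, mediator, outcome = "PHL", treatment = "SCC",
                   design = prep_config(), cfg = dml_config(),
                   controls = NULL) {
  X <- if (is.matrix(design)) design else build_design(panel, design, controls)
  fit <- joint_residual_fit(panel[[outcome]], panel[[treatment]],
                            panel[[mediator]], X, cfg,
                            panel[[cfg$cluster_col]], cfg$seed)
  c(fit[c("b_hat", "se_b", "theta_direct", "se_theta", "a_hat", "se_a")],
    list(t_b = fit$b_hat / fit$se_b,
         t_theta = fit$theta_direct / fit$se_theta,
         n_obs = nrow(panel)))
}

#' Bootstrap confidence interval for the indirect (mediated) effect
#'
#' Point estimates of the a- and b-paths come from the full sample; the
#' indirect effect is their product a*b.  Uncertainty is assessed by a
#' city-block bootstrap: whole cities are resampled with replacement
#' (preserving within-city dependence), nuisances are re-fit on each
#' replicate, and the percentile 2.5/97.5 interval of the replicated
#' products forms the 95% CI.  Replicates that fail (degenerate
#' resamples) are tolerated up to 20%.
#'
#' @inheritParams path_b
#' @param n_boot number of bootstrap replicates (the reference analysis
#'   uses 1,000).
#' @param boot_learner_params learner parameters used inside the
#'   bootstrap loop; defaults to a reduced 100-tree forest when the main
#'   learner is a random forest, to bound runtime.
#' @return object of class \code{mediation_result}.
#' @export
bootstrap_indirect <- function(panel, mediator, outcome = "PHL",
                               treatment = "SCC", design = prep_config(),
                               cfg = dml_config(), controls = NULL,
                               n_boot = 1000L, boot_learner_params = NULL) {
  X <- if (is.matrix(design)) design else build_design(panel, design, controls)
  y <- panel[[outcome]]; d <- panel[[treatment]]; m <- panel[[mediator]]
  clusters <- panel[[cfg$cluster_col]]
  full <- joint_residual_fit(y, d, m, X, cfg, clusters, cfg$seed)

  boot_cfg <- cfg
  if (is.null(boot_learner_params) && cfg$learner == "random_forest")
    boot_learner_params <- utils::modifyList(cfg$learner_params,
                                             list(num.trees = 100L))
  if (!is.null(boot_learner_params))
    boot_cfg$learner_params <- boot_learner_params

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 77L)
  uc <- unique(clusters)
  boot_est <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    draw <- sample(uc, length(uc), replace = TRUE)
    idx_list <- lapply(draw, function(ci) which(clusters == ci))
    idx <- unlist(idx_list)
    # resampled copies of the same city are distinct clusters
    new_cl <- rep(seq_along(idx_list), lengths(idx_list))
    rep_seed <- sample.int(.Machine$integer.max, 1L)
    est <- tryCatch({
      fit <- joint_residual_fit(y[idx], d[idx], m[idx],
                                X[idx, , drop = FALSE], boot_cfg,
                                new_cl, rep_seed)
      fit$a_hat * fit$b_hat
    }, error = function(e) NA_real_)
    boot_est[b] <- est
  }
  fail <- mean(is.na(boot_est))
  if (fail > 0.20)
    stop("bootstrap unstable: ", round(100 * fail), "% of replicates failed")
  ci <- unname(stats::quantile(boot_est, c(0.025, 0.975), na.rm = TRUE))
  structure(list(mediator = mediator,
                 a_hat = full$a_hat, se_a = full$se_a,
                 b_hat = full$b_hat, se_b = full$se_b,
                 theta_direct = full$theta_direct,
                 se_theta = full$se_theta,
                 indirect = full$a_hat * full$b_hat,
                 boot_ci95 = ci, n_boot = as.integer(n_boot),
                 boot_fail_rate = fail, boot_estimates = boot_est,
                 seed = cfg$seed, n_obs = nrow(panel)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> mediator ", x$mediator, " (", x$n_boot,
      " bootstrap reps)\n", sep = "")
  cat(sprintf("  a (policy -> mediator)  = %.4f (se %.4f)\n", x$a_hat, x$se_a))
  cat(sprintf("  b (mediator -> outcome) = %.4f (se %.4f)\n", x$b_hat, x$se_b))
  cat(sprintf("  direct effect           = %.4f (se %.4f)\n",
              x$theta_direct, x$se_theta))
  excl <- x$boot_ci95[1] > 0 || x$boot_ci95[2] < 0
  cat(sprintf("  indirect a*b = %.4f, 95%% bootstrap CI [%.4f, %.4f]%s\n",
              x$indirect, x$boot_ci95[1], x$boot_ci95[2],
              if (excl) " (excludes 0)" else " (contains 0)"))
  invisible(x)
}
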