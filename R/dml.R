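#' Settings for the cross-fitted partial-linear estimator
#'
#' @param n_folds number of cross-fitting folds K (>= 2).  The default
#'   K = 5 corresponds to a 4:1 train:holdout split per round; K = 4 and
#'   K = 8 give the 3:1 and 7:1 robustness variants.
#' @param learner nuisance learner: \code{"random_forest"} (default;
#'   500 trees, minimum node size 5, regression forest also for the
#'   binary treatment), \code{"gradient_boosting"} or \code{"linear"}.
#' @param learner_params named list overriding learner defaults
#'   (e.g. \code{list(num.trees = 100)}).
#' @param n_repeats number of independent cross-fitting repetitions;
#'   the point estimate is the median over repeats and the variance the
#'   median of per-repeat variances.
#' @param seed integer seed controlling fold assignment and learner
#'   randomness; identical seeds give identical results.
#' @param cluster_col column used to cluster the influence-function
#'   standard errors (default \code{"city_id"}).
#' @param cluster_folds if \code{TRUE}, whole clusters (cities) are
#'   assigned to folds, so no city straddles a train/holdout boundary.
#' @return object of class \code{dml_config}.
#' @export
dml_config <- function(n_folds = 5L, learner = "random_forest",
                       learner_params = list(), n_repeats = 1L,
                       seed = 1L, cluster_col = "city_id",
                       cluster_folds = FALSE) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  get_learner(learner)  # validate name early
  structure(list(n_folds = as.integer(n_folds), learner = learner,
                 learner_params = learner_params,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 cluster_col = cluster_col,
                 cluster_folds = isTRUE(cluster_folds)),
            class = "dml_config")
}

# Seeded K-fold assignment: a random permutation cut into contiguous
# blocks of near-equal size.  With clusters, whole clusters are permuted
# and assigned so fold boundaries never split a cluster.
make_folds <- function(n, k, clusters = NULL, cluster_folds = FALSE) {
  fold <- integer(n)
  if (cluster_folds && !is.null(clusters)) {
    uc <- unique(clusters)
    perm <- sample(length(uc))
    cf <- rep(seq_len(k), length.out = length(uc))[order(perm)]
    fold <- cf[match(clusters, uc)]
  } else {
    perm <- sample(n)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    fold[perm] <- rep(seq_len(k), times = sizes)
  }
  fold
}

#' Cross-fit the outcome and treatment nuisance functions
#'
#' Splits the sample into K folds; for each fold, learners trained on
#' the complementary folds predict the conditional expectations
#' g(X) = E[Y | X] and m(X) = E[D | X] on the held-out fold, so every
#' observation receives exactly one out-of-fold prediction.  For a
#' binary treatment, m-hat is clipped to [0, 1].  A training fold with
#' constant treatment falls back to mean prediction with a warning.
#'
#' @param y outcome vector.
#' @param d treatment vector.
#' @param X numeric design matrix from \code{\link{build_design}}.
#' @param cfg a \code{\link{dml_config}}.
#' @param clusters optional cluster ids (needed for
#'   \code{cluster_folds}).
#' @param seed seed for fold assignment and learner randomness; defaults
#'   to \code{cfg$seed}.  Identical seeds give identical folds and
#'   predictions.
#' @return list of class \code{nuisance_fit}: \code{ghat}, \code{mhat},
#'   \code{folds}, and out-of-fold fit diagnostics \code{r2_y},
#'   \code{r2_d}.
#' @export
crossfit_nuisances <- function(y, d, X, cfg = dml_config(), clusters = NULL,
                               seed = cfg$seed) {
  n <- length(y)
  stopifnot(length(d) == n, nrow(X) == n)
  if (anyNA(y) || anyNA(d) || anyNA(X)) stop("missing values in estimator input")
  if (n < 2L * cfg$n_folds) stop("need at least 2 observations per fold")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fold <- make_folds(n, cfg$n_folds, clusters, cfg$cluster_folds)
  learner <- get_learner(cfg$learner)
  binary_d <- all(d %in% c(0, 1))
  ghat <- numeric(n); mhat <- numeric(n)
  for (k in seq_len(cfg$n_folds)) {
    te <- fold == k; tr <- !te
    if (!any(te)) next
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    ghat[te] <- learner(y[tr], X[tr, , drop = FALSE],
                        X[te, , drop = FALSE], cfg$learner_params, sub_seed)
    if (stats::var(d[tr]) == 0) {
      warning("fold ", k, ": constant treatment in training folds; ",
              "using mean prediction for m-hat")
      mhat[te] <- mean(d[tr])
    } else {
      mhat[te] <- learner(d[tr], X[tr, , drop = FALSE],
                          X[te, , drop = FALSE], cfg$learner_params,
                          sub_seed + 1L)
    }
  }
  if (binary_d) mhat <- pmin(pmax(mhat, 0), 1)
  structure(list(ghat = ghat, mhat = mhat, folds = fold,
                 r2_y = 1 - mean((y - ghat)^2) / stats::var(y),
                 r2_d = if (stats::var(d) > 0)
                   1 - mean((d - mhat)^2) / stats::var(d) else NA_real_),
            class = "nuisance_fit")
}

#' Orthogonalized point estimate of the policy effect
#'
#' The residual V = D - m(X) serves as the instrument for the treatment:
#' theta-hat = sum(V * (Y - g(X))) / sum(V * D), the ratio of the two
#' score sums.  This is the partialling-out moment whose derivative with
#' respect to nuisance perturbations vanishes (Neyman orthogonality).
#'
#' @param vhat treatment residuals D - m-hat(X).
#' @param ytilde outcome residuals Y - g-hat(X).
#' @param d raw treatment vector.
#' @return theta-hat (scalar).
#' @export
estimate_theta <- function(vhat, ytilde, d) {
  stopifnot(length(vhat) == length(ytilde), length(vhat) == length(d))
  denom <- sum(vhat * d)
  if (abs(denom) < 1e-12 * length(d))
    stop("no residual treatment variation: sum(V * D) is numerically zero")
  sum(vhat * ytilde) / denom
}

# Clustered influence-function variance for a ratio-form score
# psi = r * (ytilde - theta * d) with Jacobian J = sum(r * d):
# Var(theta) = J^-2 * sum_c (sum_{i in c} psi_i)^2
cluster_if_variance <- function(psi, J, clusters) {
  cl_sums <- if (is.null(clusters)) psi else
    as.numeric(tapply(psi, clusters, sum))
  sum(cl_sums^2) / J^2
}

new_dml_result <- function(theta, var, n_obs, thetas, diagnostics, cfg,
                           estimator = "PLR") {
  se <- sqrt(var)
  structure(list(theta_hat = theta, se = se, t_stat = theta / se,
                 ci95 = c(theta - 1.96 * se, theta + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(theta / se)),
                 n_obs = n_obs, thetas = thetas,
                 diagnostics = diagnostics, config = cfg,
                 estimator = estimator),
            class = "dml_result")
}

#' Cross-fitted partial-linear double machine learning estimator
#'
#' Estimates theta in the partial-linear model
#' Y = theta * D + g(X) + U by (i) building the high-dimensional control
#' design, (ii) cross-fitting the two nuisance functions E[Y|X] and
#' E[D|X] with the configured learner, (iii) residualizing, and (iv)
#' solving the orthogonalized moment with \code{\link{estimate_theta}}.
#' Standard errors are influence-function sandwich estimates clustered
#' by city.  With \code{n_repeats > 1} the whole cross-fitting cycle is
#' repeated on fresh fold splits and aggregated by medians.
#'
#' @param panel complete long panel (no missing values).
#' @param outcome,treatment column names (defaults \code{"PHL"},
#'   \code{"SCC"}).
#' @param design either a \code{\link{prep_config}} describing how to
#'   build the design from the panel, or a prebuilt numeric matrix.
#' @param cfg a \code{\link{dml_config}}.
#' @param controls passed to \code{\link{build_design}}.
#' @return object of class \code{dml_result}: \code{theta_hat},
#'   \code{se}, \code{t_stat}, \code{ci95}, \code{p_value},
#'   \code{n_obs}, per-repeat \code{thetas}, and nuisance
#'   \code{diagnostics} (out-of-fold R-squared for both nuisances, mean
#'   treatment residual, correlation of V-hat with m-hat).
#' @examples
#' cfg <- dgp_config(n_cities = 40, n_years = 6, nonlinear_nuisance = FALSE,
#'                   mediator_paths = list(EEQ = c(a = 0, b = 0)), seed = 7)
#' panel <- generate_panel(cfg)
#' fit <- dml_plr(panel, design = prep_config(add_squares = FALSE),
#'                cfg = dml_config(learner = "linear", seed = 7))
#' fit
#' @export
dml_plr <- function(panel, outcome = "PHL", treatment = "SCC",
                    design = prep_config(), cfg = dml_config(),
                    controls = NULL) {
  X <- if (is.matrix(design)) design else build_design(panel, design, controls)
  y <- panel[[outcome]]; d <- panel[[treatment]]
  if (is.null(y) || is.null(d)) stop("outcome/treatment column not found")
  if (stats::var(d) == 0) stop("treatment has no variation")
  clusters <- panel[[cfg$cluster_col]]

  thetas <- vars <- numeric(cfg$n_repeats)
  diag_acc <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    nf <- crossfit_nuisances(y, d, X, cfg, clusters,
                             seed = cfg$seed + (r - 1L))
    vhat <- d - nf$mhat
    ytilde <- y - nf$ghat
    th <- estimate_theta(vhat, ytilde, d)
    psi <- vhat * (ytilde - th * d)
    J <- sum(vhat * d)
    thetas[r] <- th
    vars[r] <- cluster_if_variance(psi, J, clusters)
    if (r == 1L)
      diag_acc <- list(r2_y = nf$r2_y, r2_d = nf$r2_d,
                       mean_vhat = mean(vhat),
                       cor_vhat_mhat = if (stats::var(nf$mhat) > 0)
                         stats::cor(vhat, nf$mhat) else 0)
  }
  new_dml_result(stats::median(thetas), stats::median(vars),
                 length(y), thetas, diag_acc, cfg, estimator = "PLR")
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' @export
print.dml_result <- function(x, ...) {
  cat("<dml_result> ", x$estimator, " estimate (", x$config$learner,
      ", K=", x$config$n_folds, ", repeats=", x$config$n_repeats, ")\n",
      sep = "")
  cat(sprintf("  theta = %.4f%s  (se %.4f, t %.2f, 95%% CI [%.4f, %.4f], n %d)\n",
              x$theta_hat, significance_stars(x$p_value), x$se, x$t_stat,
              x$ci95[1], x$ci95[2], x$n_obs))
  d <- x$diagnostics
  if (!is.null(d))
    cat(sprintf("  nuisance R2: outcome %.3f, treatment %.3f; mean(Vhat) %.4f\n",
                d$r2_y, d$r2_d, d$mean_vhat))
  invisible(x)
}
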