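#' Build a time-varying instrument from a historical city variable
#'
#' A time-invariant city-level base (e.g. historical post-office density)
#' cannot instrument a panel treatment directly; interacting it with a
#' linear time trend yields Z_it = base_i * (year_t - trend_origin).
#'
#' @param panel long panel with \code{city_id} and \code{year}.
#' @param base_col name of the time-invariant base column.
#' @param trend_origin year subtracted from the calendar year; defaults
#'   to the year before the first panel year, so the trend runs 1..T.
#' @return numeric instrument vector aligned to the panel rows.
#' @export
build_instrument <- function(panel, base_col = "instrument_base",
                             trend_origin = NULL) {
  base <- panel[[base_col]]
  if (is.null(base)) stop("instrument base column '", base_col, "' not found")
  varies <- tapply(base, panel$city_id, function(x) max(x) - min(x))
  if (any(varies > 0))
    stop("instrument base varies within city ",
         names(varies)[which(varies > 0)[1]])
  if (is.null(trend_origin)) trend_origin <- min(panel$year) - 1L
  base * (panel$year - trend_origin)
}

#' Cross-fitted partial-linear instrumental-variable estimator
#'
#' Handles endogenous policy adoption: all three of outcome, treatment
#' and instrument are residualized on the high-dimensional controls via
#' cross-fitted learners, then theta is the residual-on-residual IV
#' ratio sum(Z-res * Y-res) / sum(Z-res * D-res).  Standard errors use
#' the IV influence function psi = Z-res * (Y-res - theta * D-res),
#' clustered by city.  The first-stage residual correlation
#' cor(Z-res, D-res) is reported as a weak-instrument diagnostic.
#'
#' @inheritParams dml_plr
#' @param instrument either the name of a column holding the instrument
#'   or a numeric vector (e.g. from \code{\link{build_instrument}}).
#' @param weak_tol refuse when |sum(Z-res * D-res)| / n falls below this
#'   tolerance (no identifying variation).
#' @return object of class \code{dml_result} with estimator
#'   \code{"PLIV"}; diagnostics add \code{first_stage_cor}.
#' @export
dml_pliv <- function(panel, outcome = "PHL", treatment = "SCC",
                     instrument = NULL, design = prep_config(),
                     cfg = dml_config(), controls = NULL,
                     weak_tol = 1e-8) {
  X <- if (is.matrix(design)) design else build_design(panel, design, controls)
  y <- panel[[outcome]]; d <- panel[[treatment]]
  z <- if (is.character(instrument)) panel[[instrument]] else instrument
  if (is.null(z)) z <- build_instrument(panel)
  n <- length(y)
  stopifnot(length(z) == n, length(d) == n)
  clusters <- panel[[cfg$cluster_col]]
  learner <- get_learner(cfg$learner)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  thetas <- vars <- numeric(cfg$n_repeats)
  diag_acc <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(cfg$seed + (r - 1L))
    fold <- make_folds(n, cfg$n_folds, clusters, cfg$cluster_folds)
    ghat <- mhat <- zhat <- numeric(n)
    for (k in seq_len(cfg$n_folds)) {
      te <- fold == k; tr <- !te
      if (!any(te)) next
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      ghat[te] <- learner(y[tr], Xtr, Xte, cfg$learner_params, sub_seed)
      mhat[te] <- if (stats::var(d[tr]) == 0) mean(d[tr]) else
        learner(d[tr], Xtr, Xte, cfg$learner_params, sub_seed + 1L)
      zhat[te] <- learner(z[tr], Xtr, Xte, cfg$learner_params, sub_seed + 2L)
    }
    if (all(d %in% c(0, 1))) mhat <- pmin(pmax(mhat, 0), 1)
    yt <- y - ghat; dt <- d - mhat; zt <- z - zhat
    J <- sum(zt * dt)
    if (abs(J) < weak_tol * n)
      stop("weak instrument: |sum(Z-res * D-res)|/n = ",
           signif(abs(J) / n, 3), " below tolerance")
    th <- sum(zt * yt) / J
    psi <- zt * (yt - th * dt)
    thetas[r] <- th
    vars[r] <- cluster_if_variance(psi, J, clusters)
    if (r == 1L)
      diag_acc <- list(
        first_stage_cor = stats::cor(zt, dt),
        r2_y = 1 - mean(yt^2) / stats::var(y),
        r2_d = if (stats::var(d) > 0) 1 - mean(dt^2) / stats::var(d) else NA_real_,
        mean_zres = mean(zt))
  }
  new_dml_result(stats::median(thetas), stats::median(vars),
                 n, thetas, diag_acc, cfg, estimator = "PLIV")
}
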