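#' Assemble a report table from fitted results
#'
#' @param fits named list of \code{dml_result} objects (or lists with
#'   the same fields).
#' @param meta optional data.frame of per-column specification metadata.
#' @return object of class \code{report_table}: a data.frame with one
#'   row per specification (coefficient, SE, t, stars, n).
#' @export
report_table <- function(fits, meta = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(spec = nm, theta = f$theta_hat, se = f$se,
               t = f$t_stat, stars = significance_stars(f$p_value),
               n = f$n_obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) out <- cbind(out, meta)
  class(out) <- c("report_table", "data.frame")
  out
}

#' @export
print.report_table <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$theta <- sprintf("%.4f%s", y$theta, y$stars)
  y$se <- sprintf("(%.4f)", y$se)
  y$t <- sprintf("%.2f", y$t)
  y$stars <- NULL
  print(y, row.names = FALSE)
  cat("stars: *** p<0.01, ** p<0.05, * p<0.10 (two-sided normal)\n")
  invisible(x)
}

report_table_markdown <- function(tab) {
  df <- as.data.frame(tab)
  df$theta <- sprintf("%.4f%s", df$theta, df$stars)
  df$se <- sprintf("(%.4f)", df$se)
  df$t <- sprintf("%.2f", df$t)
  df$stars <- NULL
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, body,
    "", "stars: *** p<0.01, ** p<0.05, * p<0.10 (two-sided normal test)")
}

#' Benchmark specification ladder
#'
#' Four cross-fitted partial-linear fits of increasing richness:
#' (1) control levels only, (2) plus squared controls, (3) plus year
#' fixed effects, (4) plus city fixed effects — the standard way of
#' showing that the estimated policy effect survives progressively
#' stricter control sets.
#'
#' @param panel prepared long panel.
#' @param cfg a \code{\link{dml_config}}.
#' @param outcome,treatment column names.
#' @return a \code{report_table} with four rows and FE flags.
#' @export
run_benchmark <- function(panel, cfg = dml_config(),
                          outcome = "PHL", treatment = "SCC") {
  specs <- list(
    controls       = prep_config(add_squares = FALSE, fe_year = FALSE, fe_city = FALSE),
    `+squares`     = prep_config(add_squares = TRUE,  fe_year = FALSE, fe_city = FALSE),
    `+year FE`     = prep_config(add_squares = TRUE,  fe_year = TRUE,  fe_city = FALSE),
    `+city FE`     = prep_config(add_squares = TRUE,  fe_year = TRUE,  fe_city = TRUE))
  fits <- lapply(specs, function(pc)
    dml_plr(panel, outcome, treatment, design = pc, cfg = cfg))
  meta <- data.frame(squares = c(FALSE, TRUE, TRUE, TRUE),
                     fe_year = c(FALSE, FALSE, TRUE, TRUE),
                     fe_city = c(FALSE, FALSE, FALSE, TRUE))
  report_table(fits, meta)
}

#' Robustness suite
#'
#' Re-estimates the benchmark specification under the enabled
#' perturbations: two winsorization presets (1%/99% and 5%/95%),
#' province-by-trend fixed effects, concurrent-policy dummies, the
#' instrumental-variable variant, alternative fold counts and the
#' gradient-boosting learner swap.
#'
#' @param panel prepared long panel.
#' @param cfg a \code{\link{dml_config}} for the benchmark estimator.
#' @param base_design the benchmark \code{\link{prep_config}}.
#' @param toggles character vector among \code{"winsor_1"},
#'   \code{"winsor_5"}, \code{"province_trend"}, \code{"policy_dummies"},
#'   \code{"iv"}, \code{"folds_4"}, \code{"folds_8"}, \code{"gradboost"}.
#' @param policy_cols binary columns used by the policy-dummy toggle.
#' @param outcome,treatment column names.
#' @return a \code{report_table}, first row the benchmark.
#' @export
run_robustness <- function(panel, cfg = dml_config(),
                           base_design = prep_config(),
                           toggles = c("winsor_1", "winsor_5",
                                       "province_trend", "iv",
                                       "folds_4", "folds_8", "gradboost"),
                           policy_cols = character(),
                           outcome = "PHL", treatment = "SCC") {
  fits <- list(
    benchmark = dml_plr(panel, outcome, treatment, base_design, cfg))
  recfg <- function(cfg, ...) {
    args <- list(...)
    for (nm in names(args)) cfg[[nm]] <- args[[nm]]
    cfg
  }
  for (tg in toggles) {
    fits[[tg]] <- switch(tg,
      winsor_1 = dml_plr(winsorize(panel, c(0.01, 0.99)), outcome, treatment,
                         base_design, cfg),
      winsor_5 = dml_plr(winsorize(panel, c(0.05, 0.95)), outcome, treatment,
                         base_design, cfg),
      province_trend = {
        pc <- base_design; pc$province_trend <- TRUE
        dml_plr(panel, outcome, treatment, pc, cfg)
      },
      policy_dummies = {
        pc <- base_design; pc$policy_dummies <- policy_cols
        dml_plr(panel, outcome, treatment, pc, cfg)
      },
      iv = dml_pliv(panel, outcome, treatment,
                    instrument = build_instrument(panel),
                    design = base_design, cfg = cfg),
      folds_4 = dml_plr(panel, outcome, treatment, base_design,
                        recfg(cfg, n_folds = 4L)),
      folds_8 = dml_plr(panel, outcome, treatment, base_design,
                        recfg(cfg, n_folds = 8L)),
      gradboost = dml_plr(panel, outcome, treatment, base_design,
                          recfg(cfg, learner = "gradient_boosting")),
      stop("unknown robustness toggle '", tg, "'"))
  }
  tab <- report_table(fits)
  bench <- fits$benchmark
  tab$same_sign <- sign(tab$theta) == sign(bench$theta_hat)
  tab$delta_in_bench_se <- (tab$theta - bench$theta_hat) / bench$se
  tab
}

#' Subgroup heterogeneity analysis
#'
#' Separate estimates per level of each grouping variable (region, city
#' size, regulation intensity), plus a per-adoption-batch analysis that
#' compares each wave's adopters to never-treated cities only, keeping
#' other waves out of the control group.  Subgroups too small to
#' cross-fit are skipped with a warning.
#'
#' @param panel prepared long panel with group-label columns.
#' @param cfg a \code{\link{dml_config}}.
#' @param design the \code{\link{prep_config}} used for every subgroup.
#' @param group_vars label columns to split on.
#' @param batch_col adoption-batch column (\code{"none"} = never treated).
#' @param outcome,treatment column names.
#' @return named list of \code{report_table}s, one per grouping variable.
#' @export
run_heterogeneity <- function(panel, cfg = dml_config(),
                              design = prep_config(),
                              group_vars = c("region", "size", "regulation"),
                              batch_col = "batch",
                              outcome = "PHL", treatment = "SCC") {
  fit_sub <- function(sub, label) {
    if (nrow(sub) < 2L * cfg$n_folds ||
        stats::var(sub[[treatment]]) == 0 ||
        length(unique(sub$city_id)) < cfg$n_folds) {
      warning("subgroup '", label, "' too small or without treatment variation; skipped")
      return(NULL)
    }
    dml_plr(sub, outcome, treatment, design, cfg)
  }
  out <- list()
  for (gv in intersect(group_vars, names(panel))) {
    fits <- list()
    for (lv in sort(unique(panel[[gv]]))) {
      f <- fit_sub(panel[panel[[gv]] == lv, , drop = FALSE],
                   paste0(gv, "=", lv))
      if (!is.null(f)) fits[[lv]] <- f
    }
    if (length(fits)) out[[gv]] <- report_table(fits)
  }
  if (batch_col %in% names(panel)) {
    fits <- list()
    for (bt in setdiff(sort(unique(panel[[batch_col]])), "none")) {
      sub <- panel[panel[[batch_col]] %in% c(bt, "none"), , drop = FALSE]
      f <- fit_sub(sub, paste0("batch ", bt, " vs never-treated"))
      if (!is.null(f)) fits[[paste0("batch_", bt)]] <- f
    }
    if (length(fits)) out$batch <- report_table(fits)
  }
  out
}

#' Run the full simulated study from one configuration
#'
#' End-to-end orchestration: simulate (or load) the panel, optionally
#' build the composite index from raw indicators, prepare the design,
#' then run the benchmark ladder, the robustness suite, mediation for
#' every listed mediator and the heterogeneity splits.  Every number in
#' the output bundle is a deterministic function of the configuration,
#' and a manifest records seeds and configuration for reproducibility.
#'
#' @param config either a path to a YAML file or a nested list with
#'   blocks \code{dgp} (arguments of \code{\link{dgp_config}}; or
#'   \code{panel_file}, a CSV path), \code{prep}
#'   (\code{\link{prep_config}} arguments), \code{dml}
#'   (\code{\link{dml_config}} arguments), \code{mediators} (character),
#'   \code{robustness} (toggle names), \code{heterogeneity} (group
#'   variables), \code{n_boot}, \code{use_entropy_index} (rebuild the
#'   outcome from simulated indicators), and \code{seed}.
#' @param out_dir optional directory: writes \code{results/*.json},
#'   \code{tables/*.md} and \code{manifest.json}.
#' @return invisible list with the panel, every table and result object,
#'   and the manifest.
#' @export
run_full_study <- function(config, out_dir = NULL) {
  cf <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cf$seed %||% 1L
  t_start <- Sys.time()

  ## 1. panel
  if (!is.null(cf$panel_file)) {
    panel <- utils::read.csv(cf$panel_file, stringsAsFactors = FALSE)
    class(panel) <- c("panel_dataset", "data.frame")
    dgp <- NULL
  } else {
    dgp_args <- cf$dgp %||% list()
    if (!is.null(dgp_args$adoption_waves))
      dgp_args$adoption_waves <- as.data.frame(dgp_args$adoption_waves)
    if (!is.null(dgp_args$mediator_paths))
      dgp_args$mediator_paths <- lapply(dgp_args$mediator_paths, function(m) {
        m <- unlist(m)
        # YAML writes named pairs as plain [a, b] sequences
        if (is.null(names(m)) && length(m) == 2) names(m) <- c("a", "b")
        m
      })
    if (is.null(dgp_args$seed)) dgp_args$seed <- seed
    dgp <- do.call(dgp_config, dgp_args)
    panel <- generate_panel(dgp)
  }
  validate_panel(panel)

  ## 2. optional entropy index as outcome
  index_res <- NULL
  if (isTRUE(cf$use_entropy_index) && !is.null(dgp)) {
    ind <- generate_indicator_table(dgp)
    index_res <- composite_index(ind[, attr(ind, "specs")$name],
                                 attr(ind, "specs"))
    key <- paste(panel$city_id, panel$year)
    panel$PHL <- index_res$index[match(key, paste(ind$city_id, ind$year))]
  }

  ## 3. prep
  prep <- do.call(prep_config, cf$prep %||% list())
  panel <- prepare_panel(panel, prep)

  ## 4. estimators
  dml_args <- cf$dml %||% list()
  if (is.null(dml_args$seed)) dml_args$seed <- seed
  dcfg <- do.call(dml_config, dml_args)

  results <- list(benchmark = run_benchmark(panel, dcfg))
  if (length(cf$robustness %||% character()))
    results$robustness <- run_robustness(panel, dcfg,
                                         toggles = cf$robustness,
                                         policy_cols = cf$policy_cols %||% character())
  if (length(cf$mediators %||% character())) {
    results$mediation <- lapply(cf$mediators, function(md)
      bootstrap_indirect(panel, md, cfg = dcfg,
                         design = do.call(prep_config, cf$prep %||% list()),
                         n_boot = cf$n_boot %||% 1000L))
    names(results$mediation) <- cf$mediators
  }
  if (length(cf$heterogeneity %||% character()))
    results$heterogeneity <- run_heterogeneity(panel, dcfg,
                                               group_vars = cf$heterogeneity)

  manifest <- list(seed = seed, config = cf,
                   n_rows = nrow(panel),
                   n_cities = length(unique(panel$city_id)),
                   generated = !is.null(dgp),
                   runtime_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))

  if (!is.null(out_dir)) write_study_bundle(results, index_res, manifest, out_dir)
  invisible(c(results, list(panel = panel, index = index_res,
                            manifest = manifest)))
}

# strip non-deterministic / bulky fields before serializing
result_json_payload <- function(results) {
  clean_dml <- function(f) f[c("estimator", "theta_hat", "se", "t_stat",
                               "ci95", "p_value", "n_obs", "thetas")]
  payload <- list()
  for (nm in names(results)) {
    obj <- results[[nm]]
    payload[[nm]] <-
      if (inherits(obj, "report_table")) as.data.frame(obj)
      else if (nm == "mediation")
        lapply(obj, function(m) m[c("mediator", "a_hat", "se_a", "b_hat",
                                    "se_b", "theta_direct", "se_theta",
                                    "indirect", "boot_ci95", "n_boot")])
      else if (nm == "heterogeneity") lapply(obj, as.data.frame)
      else if (inherits(obj, "dml_result")) clean_dml(obj)
      else obj
  }
  payload
}

write_study_bundle <- function(results, index_res, manifest, out_dir) {
  dir.create(file.path(out_dir, "results"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  payload <- result_json_payload(results)
  jsonlite::write_json(payload, file.path(out_dir, "results", "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(index_res))
    jsonlite::write_json(list(weights = as.list(index_res$weights),
                              index_summary = summary(index_res$index)),
                         file.path(out_dir, "results", "index.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  for (nm in names(results)) {
    obj <- results[[nm]]
    tabs <- if (inherits(obj, "report_table")) list(obj)
            else if (nm == "heterogeneity") obj else NULL
    if (is.null(tabs)) next
    lines <- unlist(lapply(seq_along(tabs), function(i) {
      ttl <- if (length(tabs) > 1) paste0("## ", names(tabs)[i]) else paste0("## ", nm)
      c(ttl, "", report_table_markdown(tabs[[i]]), "")
    }))
    writeLines(lines, file.path(out_dir, "tables", paste0(nm, ".md")))
  }
  if (!is.null(results$mediation)) {
    lines <- unlist(lapply(results$mediation, function(m) c(
      paste0("## mediator ", m$mediator),
      sprintf("a = %.4f (se %.4f); b = %.4f (se %.4f); direct = %.4f (se %.4f)",
              m$a_hat, m$se_a, m$b_hat, m$se_b, m$theta_direct, m$se_theta),
      sprintf("indirect a*b = %.4f, 95%% bootstrap CI [%.4f, %.4f], %d reps",
              m$indirect, m$boot_ci95[1], m$boot_ci95[2], m$n_boot), "")))
    writeLines(lines, file.path(out_dir, "tables", "mediation.md"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
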