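# compact study configuration used by the pipeline tests
small_study <- function(seed = 1) {
  list(
    seed = seed,
    dgp = list(n_cities = 50, n_years = 8,
               adoption_waves = list(year = c(2010L, 2011L),
                                     fraction = c(0.25, 0.25)),
               nonlinear_nuisance = FALSE,
               mediator_paths = list(EEQ = c(a = 0.3, b = 0.3)),
               fe_sd_city = 0, fe_sd_year = 0),
    prep = list(add_squares = FALSE, fe_year = TRUE),
    dml = list(learner = "linear", n_folds = 5),
    mediators = "EEQ",
    n_boot = 40,
    robustness = c("winsor_5", "folds_4"),
    heterogeneity = c("region", "size"))
}

test_that("benchmark ladder has four specifications with the right flags", {
  p <- generate_panel(linear_cfg(n_cities = 50, n_years = 8, seed = 101))
  tab <- run_benchmark(p, lin_dml(seed = 1))
  expect_s3_class(tab, "report_table")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$fe_year, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tab$fe_city, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tab$squares, c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(tab$n == nrow(p)))
  # stars follow the two-sided normal convention
  pvals <- 2 * stats::pnorm(-abs(tab$t))
  expect_equal(tab$stars == "***", pvals < 0.01)
})

test_that("robustness variants stay close to the benchmark on a clean DGP", {
  p <- generate_panel(linear_cfg(n_cities = 80, n_years = 8, theta = 0.3,
                                 seed = 111))
  p$noise_dummy <- as.integer(seq_len(nrow(p)) %% 7 == 0)  # irrelevant policy
  tab <- run_robustness(p, lin_dml(seed = 2),
                        base_design = prep_config(add_squares = FALSE),
                        toggles = c("winsor_1", "winsor_5", "province_trend",
                                    "policy_dummies", "folds_4", "folds_8"),
                        policy_cols = "noise_dummy")
  expect_true(all(tab$same_sign))
  win <- tab[tab$spec %in% c("winsor_1", "winsor_5"), ]
  expect_true(all(abs(win$delta_in_bench_se) < 3))
  pol <- tab[tab$spec == "policy_dummies", ]
  expect_lt(abs(pol$delta_in_bench_se), 1)
})

test_that("heterogeneity splits recover group-specific effects", {
  # homogeneous effect: subgroup estimates agree within sampling error
  p <- generate_panel(linear_cfg(n_cities = 120, n_years = 8, theta = 0.3,
                                 seed = 121))
  het <- run_heterogeneity(p, lin_dml(seed = 3),
                           design = prep_config(add_squares = FALSE),
                           group_vars = c("size", "regulation"))
  expect_true(all(c("size", "regulation", "batch") %in% names(het)))
  for (tab in het) {
    expect_s3_class(tab, "report_table")
    expect_true(all(tab$n > 0))
  }
  sz <- het$size
  spread <- abs(diff(sz$theta))
  expect_lt(spread, 3 * sqrt(sum(sz$se^2)))
  # every batch compares one wave's adopters to never-treated only
  expect_equal(sort(het$batch$spec), c("batch_1", "batch_2", "batch_3"))
})

test_that("tiny subgroups are skipped with a warning", {
  p <- generate_panel(linear_cfg(n_cities = 40, n_years = 6, seed = 131))
  p$size[p$city_id <= 2] <- "tiny_level"
  p$size[p$city_id > 2] <- "rest"
  expect_warning(
    het <- run_heterogeneity(p, lin_dml(seed = 1),
                             design = prep_config(add_squares = FALSE),
                             group_vars = "size"),
    "skipped")
})

test_that("full study runs end-to-end and is bit-identical on re-run", {
  dir1 <- file.path(tempdir(), "study_a")
  dir2 <- file.path(tempdir(), "study_b")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  r1 <- run_full_study(small_study(seed = 7), out_dir = dir1)
  r2 <- run_full_study(small_study(seed = 7), out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "results", "study.json")),
                   readLines(file.path(dir2, "results", "study.json")))
  for (f in list.files(file.path(dir1, "tables")))
    expect_identical(readLines(file.path(dir1, "tables", f)),
                     readLines(file.path(dir2, "tables", f)))
  # report numbers trace back to the stored fits
  expect_equal(r1$benchmark$theta[4],
               jsonlite::read_json(file.path(dir1, "results",
                                             "study.json"))$benchmark[[4]]$theta)
  expect_s3_class(r1$mediation$EEQ, "mediation_result")
  expect_true(file.exists(file.path(dir1, "manifest.json")))
})

test_that("dropping the mediator list skips only the mediation stage", {
  cf <- small_study(seed = 8)
  cf$mediators <- NULL
  cf$robustness <- NULL
  res <- run_full_study(cf)
  expect_null(res$mediation)
  expect_s3_class(res$benchmark, "report_table")
  expect_false(is.null(res$heterogeneity))
})

test_that("entropy-index outcome mode rebuilds PHL from indicators", {
  cf <- small_study(seed = 9)
  cf$use_entropy_index <- TRUE
  cf$mediators <- NULL; cf$robustness <- NULL; cf$heterogeneity <- NULL
  res <- run_full_study(cf)
  expect_true(all(res$panel$PHL >= 0 & res$panel$PHL <= 1))
  expect_equal(sum(res$index$weights), 1, tolerance = 1e-12)
})

test_that("study config round-trips through a YAML file", {
  cf <- small_study(seed = 10)
  cf$mediators <- NULL; cf$robustness <- NULL; cf$heterogeneity <- NULL
  yml <- file.path(tempdir(), "study.yaml")
  on.exit(unlink(yml), add = TRUE)
  yaml::write_yaml(cf, yml)
  res_file <- run_full_study(yml)
  res_list <- run_full_study(cf)
  expect_equal(res_file$benchmark$theta, res_list$benchmark$theta)
})
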