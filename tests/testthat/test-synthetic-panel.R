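test_that("panel bookkeeping: balance, wave sizes, monotone treatment", {
  cfg <- dgp_config(n_cities = 270, n_years = 14, seed = 11)
  p <- generate_panel(cfg)
  expect_s3_class(p, "panel_dataset")
  expect_equal(nrow(p), 3780)
  expect_silent(validate_panel(p))
  # floor(fraction * n) adopters per wave, remainder never treated
  first <- p[!duplicated(p$city_id), ]
  expect_equal(unname(table(first$batch)[c("1", "2", "3")]),
               c(floor(0.20 * 270), floor(0.15 * 270), floor(0.15 * 270)),
               ignore_attr = TRUE)
  # absorbing state within every city
  by_city <- split(p$SCC[order(p$city_id, p$year)],
                   p$city_id[order(p$city_id, p$year)])
  expect_true(all(vapply(by_city, function(d) all(diff(d) >= 0), logical(1))))
})

test_that("same seed gives bitwise-identical panels, different seed differs", {
  w6 <- data.frame(year = c(2009L, 2010L), fraction = c(0.3, 0.2))
  cfg <- dgp_config(n_cities = 40, n_years = 6, adoption_waves = w6, seed = 5)
  expect_identical(generate_panel(cfg), generate_panel(cfg))
  cfg2 <- dgp_config(n_cities = 40, n_years = 6, adoption_waves = w6, seed = 6)
  expect_false(identical(generate_panel(cfg)$PHL, generate_panel(cfg2)$PHL))
})

test_that("null effect without confounding: treated-untreated gap near zero", {
  diffs <- vapply(1:30, function(r) {
    cfg <- dgp_config(n_cities = 80, n_years = 8, theta_true = 0,
                      confounding_strength = 0, instrument_strength = 0,
                      adoption_waves = data.frame(year = 2010L, fraction = 0.5),
                      mediator_paths = paths_off,
                      nonlinear_nuisance = FALSE, seed = 100 + r)
    p <- generate_panel(cfg)
    mean(p$PHL[p$SCC == 1]) - mean(p$PHL[p$SCC == 0])
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se + 0.02)
})

test_that("OLS recovers theta on a linear unconfounded-FE DGP", {
  cfg <- linear_cfg(n_cities = 120, n_years = 10, theta = 0.5, seed = 21)
  p <- generate_panel(cfg)
  X <- as.matrix(p[grep("^X[0-9]+$", names(p))])
  fit <- stats::lm(p$PHL ~ p$SCC + X)
  est <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("true_effects is plain arithmetic on the config", {
  cfg <- dgp_config(theta_true = 0.15,
                    mediator_paths = list(M1 = c(a = 0.2, b = 0.5),
                                          M2 = c(a = 0.1, b = 0.3)))
  te <- true_effects(cfg)
  expect_equal(unname(te$indirect), c(0.10, 0.03))
  expect_equal(te$total, 0.15 + 0.13)
  cfg0 <- dgp_config(mediator_paths = list(M1 = c(a = 0, b = 0)))
  expect_equal(unname(true_effects(cfg0)$indirect), 0)
})

test_that("config invariants are enforced", {
  expect_error(dgp_config(adoption_waves = data.frame(
    year = c(2010L, 2011L), fraction = c(0.7, 0.5))), "sum to more than 1")
  expect_error(dgp_config(adoption_waves = data.frame(
    year = 2030L, fraction = 0.2)), "inside")
  expect_error(dgp_config(noise_sd = 0), "noise_sd")
  expect_error(dgp_config(endogeneity_rho = 1.5), "endogeneity_rho")
  # degenerate design refused at generation time
  expect_error(generate_panel(dgp_config(n_cities = 2, n_years = 2,
                                         confounder_dim = 3,
                                         adoption_waves = data.frame(
                                           year = 2008L, fraction = 0.5))),
               "degenerate")
})

test_that("pre-treatment trends of adopters and never-adopters are parallel
           when adoption is unconfounded", {
  gaps <- vapply(1:60, function(r) {
    cfg <- dgp_config(n_cities = 60, n_years = 8, theta_true = 0.2,
                      confounding_strength = 0, instrument_strength = 0,
                      endogeneity_rho = 0, mediator_paths = paths_off,
                      adoption_waves = data.frame(year = 2011L, fraction = 0.5),
                      nonlinear_nuisance = FALSE, seed = 300 + r)
    p <- generate_panel(cfg)
    pre <- p[p$year < 2011, ]
    ever <- tapply(p$SCC, p$city_id, max)
    # difference of pre-period outcome slopes between eventual groups
    sl <- function(sub) unname(stats::coef(stats::lm(PHL ~ year, sub))[2])
    sl(pre[ever[as.character(pre$city_id)] == 1, ]) -
      sl(pre[ever[as.character(pre$city_id)] == 0, ])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)) + 0.005)
})

test_that("index-scale outcome is bounded, right-skewed, clip fraction logged", {
  cfg <- dgp_config(n_cities = 270, n_years = 14, index_scale = TRUE, seed = 9)
  p <- generate_panel(cfg)
  expect_true(all(p$PHL >= 0 & p$PHL <= 1))
  expect_gt(mean(p$PHL), stats::median(p$PHL))  # right skew
  expect_true(is.finite(attr(p, "clip_fraction")))
})

test_that("indicator table: five columns, latent-driven, deterministic", {
  waves4 <- data.frame(year = 2009L, fraction = 0.3)
  cfg <- dgp_config(n_cities = 50, n_years = 4, seed = 13,
                    adoption_waves = waves4)
  tab <- generate_indicator_table(cfg)
  specs <- attr(tab, "specs")
  expect_equal(nrow(specs), 5)
  expect_equal(specs$direction[specs$name == "infectious_incidence"], "negative")
  expect_true(all(as.matrix(tab[specs$name]) > 0))
  expect_identical(tab, generate_indicator_table(cfg))
  # zero indicator noise: composite index is a strictly monotone transform
  # of the latent health factor
  cfg0 <- dgp_config(n_cities = 50, n_years = 4, indicator_noise_sd = 0,
                     seed = 13, adoption_waves = waves4)
  tab0 <- generate_indicator_table(cfg0)
  ci <- composite_index(tab0[specs$name], specs)
  expect_equal(stats::cor(ci$index, attr(tab0, "latent"), method = "spearman"), 1)
})
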