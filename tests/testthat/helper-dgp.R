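# Shared fixtures: small DGP configurations used across test files.

# mediator paths that leave the outcome untouched, so the partial-linear
# estimand equals theta_true exactly
paths_off <- list(EEQ = c(a = 0.3, b = 0), ISL = c(a = 0.2, b = 0),
                  HWS = c(a = 0.2, b = 0))

# small linear DGP: linear nuisance, no fixed effects, no outcome-side
# mediator paths -- the setting in which OLS partialling is the exact oracle
linear_cfg <- function(n_cities = 60, n_years = 8, theta = 0.5, seed = 1,
                       ...) {
  dgp_config(n_cities = n_cities, n_years = n_years, theta_true = theta,
             start_year = 2007,
             adoption_waves = data.frame(year = c(2010L, 2011L, 2012L),
                                         fraction = c(0.20, 0.15, 0.15)),
             nonlinear_nuisance = FALSE, mediator_paths = paths_off,
             fe_sd_city = 0, fe_sd_year = 0, seed = seed, ...)
}

# Frisch-Waugh-Lovell oracle: OLS coefficient of d in lm(y ~ d + X)
fwl_oracle <- function(y, d, X) {
  unname(stats::coef(stats::lm(y ~ d + X))[2])
}

# linear-learner estimator config used in most oracle tests
lin_dml <- function(seed = 1, ...) {
  dml_config(learner = "linear", seed = seed, ...)
}
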