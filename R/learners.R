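# Internal nuisance-learner interface: every learner is a function
# fit_predict(y_train, X_train, X_test, params, seed) -> numeric predictions.
# Learners are regression learners throughout; a binary treatment's
# conditional expectation is learned as a regression and clipped to [0,1].

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_predict_linear <- function(y, Xtr, Xte, params = list(), seed = NULL) {
  fit <- stats::lm.fit(cbind(1, Xtr), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0          # rank-deficient columns contribute nothing
  drop(cbind(1, Xte) %*% co)
}

fit_predict_random_forest <- function(y, Xtr, Xte, params = list(), seed = 1L) {
  fit <- ranger::ranger(
    y = y, x = Xtr,
    num.trees = params$num.trees %||% 500L,
    min.node.size = params$min.node.size %||% 5L,
    mtry = params$mtry %||% NULL,
    num.threads = 1L, seed = seed, verbose = FALSE)
  stats::predict(fit, data = Xte, num.threads = 1L)$predictions
}

fit_predict_gradient_boosting <- function(y, Xtr, Xte, params = list(), seed = 1L) {
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(eta = params$eta %||% 0.1,
                  max_depth = params$max_depth %||% 3L,
                  subsample = params$subsample %||% 1,
                  objective = "reg:squarederror",
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(Xtr, label = y),
    nrounds = params$nrounds %||% 100L, verbose = 0)
  stats::predict(booster, xgboost::xgb.DMatrix(Xte))
}

get_learner <- function(name) {
  switch(name,
         linear = fit_predict_linear,
         random_forest = fit_predict_random_forest,
         gradient_boosting = fit_predict_gradient_boosting,
         stop("unknown learner '", name,
              "'; use linear, random_forest or gradient_boosting"))
}
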