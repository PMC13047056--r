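#' Configuration of the synthetic panel data-generating process
#'
#' Defines the ground truth of a staggered-adoption city-by-year panel:
#' a binary policy switches on in waves and stays on (absorbing state),
#' the outcome is a partial-linear function of the treatment, a
#' (possibly nonlinear) confounding function of high-dimensional
#' controls, mediator channels, two-way fixed effects and noise.
#' Treatment take-up is not random: cities are ranked on an adoption
#' index that loads on the confounders (strength
#' \code{confounding_strength}), on a time-invariant historical
#' instrument (strength \code{instrument_strength}) and on an adoption
#' shock that can be correlated with the outcome error
#' (\code{endogeneity_rho}), which is what the instrumental-variable
#' estimator is there to repair.
#'
#' @param n_cities,n_years panel dimensions (default 270 cities, 14 years).
#' @param start_year first calendar year of the panel.
#' @param theta_true direct treatment effect on the outcome scale.
#' @param adoption_waves data.frame with columns \code{year} and
#'   \code{fraction}: each wave treats \code{floor(fraction * n_cities)}
#'   of the not-yet-treated cities, highest adoption index first;
#'   fractions must sum to at most 1 and wave years must fall inside the
#'   panel.  Remaining cities are never treated.
#' @param confounder_dim number of control variables \code{X1..Xk}.
#' @param confounding_strength loading of the confounders on the
#'   adoption index (0 = random adoption).
#' @param nonlinear_nuisance if \code{TRUE} the outcome nuisance g(X)
#'   (and the adoption index) include squares, pairwise products of the
#'   first three confounders and a threshold term; otherwise g is linear.
#' @param mediator_paths named list; each element \code{c(a =, b =)}
#'   gives the treatment-to-mediator and mediator-to-outcome path of one
#'   mediator.  Defaults to the three channels EEQ (ecological
#'   environment quality), ISL (innovation service level) and HWS
#'   (health workforce structure).
#' @param endogeneity_rho correlation in [-1, 1] between the city
#'   adoption shock and a city-level outcome shock (loading 0.3).
#' @param instrument_strength loading of the standardized historical
#'   instrument base on the adoption index.  The instrument never enters
#'   the outcome equation, so exclusion holds by construction.
#' @param fe_sd_city,fe_sd_year standard deviations of the city and year
#'   effects; year effects follow a mild linear trend plus noise.
#' @param noise_sd idiosyncratic outcome noise standard deviation (> 0).
#'   The nuisance g(X) is rescaled so that sd(g) equals \code{noise_sd},
#'   which makes naive linear OLS visibly biased when g is nonlinear.
#' @param index_scale if \code{TRUE} the outcome is mapped to the unit
#'   interval as \code{0.16 * exp(latent)} clipped to [0, 1], giving the
#'   extreme right-skewed bounded index shape typical of composite
#'   public-health indices; the clipped fraction is recorded as an
#'   attribute.  Default \code{FALSE} keeps the linear scale so that
#'   closed-form oracles apply.
#' @param indicator_noise_sd noise on the raw indicator table produced by
#'   \code{\link{generate_indicator_table}}.
#' @param seed integer seed; the generated panel is a deterministic
#'   function of the full configuration.
#' @return an object of class \code{dgp_config} (a validated list).
#' @seealso \code{\link{generate_panel}}, \code{\link{true_effects}}
#' @export
dgp_config <- function(n_cities = 270L,
                       n_years = 14L,
                       start_year = 2007L,
                       theta_true = 0.15,
                       adoption_waves = data.frame(
                         year = c(2012L, 2013L, 2014L),
                         fraction = c(0.20, 0.15, 0.15)),
                       confounder_dim = 6L,
                       confounding_strength = 1.0,
                       nonlinear_nuisance = TRUE,
                       mediator_paths = list(
                         EEQ = c(a = 0.30, b = 0.15),
                         ISL = c(a = 0.20, b = 0.10),
                         HWS = c(a = 0.20, b = 0.10)),
                       endogeneity_rho = 0,
                       instrument_strength = 0.5,
                       fe_sd_city = 0.10,
                       fe_sd_year = 0.05,
                       noise_sd = 0.20,
                       index_scale = FALSE,
                       indicator_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_cities = as.integer(n_cities), n_years = as.integer(n_years),
    start_year = as.integer(start_year), theta_true = theta_true,
    adoption_waves = as.data.frame(adoption_waves),
    confounder_dim = as.integer(confounder_dim),
    confounding_strength = confounding_strength,
    nonlinear_nuisance = isTRUE(nonlinear_nuisance),
    mediator_paths = mediator_paths,
    endogeneity_rho = endogeneity_rho,
    instrument_strength = instrument_strength,
    fe_sd_city = fe_sd_city, fe_sd_year = fe_sd_year,
    noise_sd = noise_sd, index_scale = isTRUE(index_scale),
    indicator_noise_sd = indicator_noise_sd,
    seed = as.integer(seed))
  class(cfg) <- "dgp_config"
  validate_dgp_config(cfg)
  cfg
}

validate_dgp_config <- function(cfg) {
  stopifnot(cfg$n_cities >= 1L, cfg$n_years >= 1L, cfg$confounder_dim >= 1L)
  w <- cfg$adoption_waves
  if (nrow(w) > 0) {
    if (!all(c("year", "fraction") %in% names(w)))
      stop("adoption_waves needs columns 'year' and 'fraction'")
    if (sum(w$fraction) > 1 + 1e-12)
      stop("adoption wave fractions sum to more than 1")
    yr_ok <- w$year >= cfg$start_year & w$year < cfg$start_year + cfg$n_years
    if (!all(yr_ok))
      stop("adoption wave years must lie inside [start_year, start_year + n_years)")
  }
  if (!all(is.finite(c(cfg$theta_true, cfg$endogeneity_rho,
                       unlist(cfg$mediator_paths)))))
    stop("theta_true, mediator paths and endogeneity_rho must be finite")
  if (abs(cfg$endogeneity_rho) > 1) stop("endogeneity_rho must be in [-1, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$confounding_strength < 0 || cfg$instrument_strength < 0 ||
      cfg$fe_sd_city < 0 || cfg$fe_sd_year < 0)
    stop("strength and sd parameters must be >= 0")
  for (m in cfg$mediator_paths)
    if (!all(c("a", "b") %in% names(m)))
      stop("each mediator path needs named components 'a' and 'b'")
  invisible(cfg)
}

# loading of the city-level outcome shock eta used by the endogeneity channel
.ETA_SD <- 0.3

# confounding surface shared by the outcome nuisance and the adoption
# index: linear combination of the leading confounders, plus the fixed
# nonlinear menu (centered squares, pairwise products of the first three
# columns, one threshold indicator) when requested
nuisance_surface <- function(X, nonlinear) {
  p <- ncol(X)
  gamma <- 0.8 * (-1)^(seq_len(p) + 1) / sqrt(seq_len(p))
  g <- drop(X %*% gamma)
  if (nonlinear) {
    k <- min(3L, p)
    for (j in seq_len(k)) g <- g + 0.5 * (X[, j]^2 - 1)
    if (k >= 2) g <- g + 0.6 * X[, 1] * X[, 2]
    if (k >= 3) g <- g + 0.6 * X[, 1] * X[, 3] + 0.6 * X[, 2] * X[, 3]
    g <- g + 0.8 * (X[, 1] > 0.5)
  }
  g
}

# region shares approximate the east/central/west/northeast composition
# of the Chinese prefecture-city panel the generator emulates
.REGION_LEVELS <- c("east", "central", "west", "northeast")
.REGION_SHARES <- c(0.32, 0.30, 0.27, 0.11)

#' Generate a staggered-adoption panel with known causal structure
#'
#' Draws a balanced city-by-year panel from the data-generating process in
#' \code{cfg}.  Treatment is an absorbing state assigned in waves by
#' ranking cities on an adoption index; the outcome follows
#' \deqn{Y_{it} = \theta D_{it} + g(X_{it}) + \sum_m b_m M_{mit} +
#'   \alpha_i + \tau_t + 0.3\,\eta_i + \varepsilon_{it}}
#' with mediators \eqn{M_{mit} = a_m D_{it} + h_m(X_{it}) + e_{mit}}.
#' The same seed always reproduces the identical panel.
#'
#' @param cfg a \code{\link{dgp_config}}.
#' @return a \code{data.frame} of class \code{panel_dataset} with columns
#'   \code{city_id, province_id, year, PHL, SCC, X1..Xk}, one column per
#'   mediator, group labels (\code{region, size, regulation, batch}) and
#'   \code{instrument_base}.  Attributes: \code{dgp_config},
#'   \code{true_effects}, \code{clip_fraction} (when \code{index_scale}).
#' @export
generate_panel <- function(cfg) {
  validate_dgp_config(cfg)
  N <- cfg$n_cities; TT <- cfg$n_years; p <- cfg$confounder_dim
  if (N * TT < 2L * p)
    stop("degenerate design: n_cities * n_years < 2 * confounder_dim")
  years <- cfg$start_year + seq_len(TT) - 1L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  ## city-level structure
  n_prov <- max(1L, round(N / 9))
  province_id <- sort(rep_len(seq_len(n_prov), N))
  prov_region <- .REGION_LEVELS[
    pmin(4L, findInterval(seq_len(n_prov) / n_prov,
                          cumsum(.REGION_SHARES), left.open = TRUE) + 1L)]
  region <- prov_region[province_id]
  size <- ifelse(stats::runif(N) < 0.3, "large", "medium_small")
  regulation <- ifelse(stats::runif(N) < 0.5, "high", "low")

  xi <- matrix(stats::rnorm(N * p, sd = sqrt(0.75)), N, p)      # city component
  instrument_base <- exp(stats::rnorm(N, sd = 0.5))             # historical density
  z_std <- as.numeric(scale(log(instrument_base)))
  eta <- stats::rnorm(N)                                        # outcome shock
  rho <- cfg$endogeneity_rho
  w_shock <- stats::rnorm(N)
  u <- rho * eta + sqrt(1 - rho^2) * w_shock                    # adoption shock

  ## adoption index and wave assignment
  s <- nuisance_surface(xi, cfg$nonlinear_nuisance)
  s <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  adopt_idx <- cfg$confounding_strength * s +
    cfg$instrument_strength * z_std + u
  waves <- cfg$adoption_waves
  adopt_year <- rep(NA_integer_, N)
  batch <- rep("none", N)
  if (nrow(waves) > 0) {
    ord <- order(adopt_idx, decreasing = TRUE)
    pos <- 0L
    for (wv in seq_len(nrow(waves))) {
      n_w <- floor(waves$fraction[wv] * N)
      if (n_w > 0) {
        sel <- ord[pos + seq_len(n_w)]
        adopt_year[sel] <- as.integer(waves$year[wv])
        batch[sel] <- as.character(wv)
        pos <- pos + n_w
      }
    }
  }

  ## panel-level draws
  n <- N * TT
  city_id <- rep(seq_len(N), each = TT)
  year <- rep(years, times = N)
  X <- xi[city_id, , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = sqrt(0.25)), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  D <- as.integer(year >= adopt_year[city_id] & !is.na(adopt_year[city_id]))

  alpha <- stats::rnorm(N, sd = cfg$fe_sd_city)
  trend <- seq_len(TT) - (TT + 1) / 2
  trend <- if (stats::sd(trend) > 0) trend / stats::sd(trend) else trend
  tau <- cfg$fe_sd_year * (0.6 * trend + 0.8 * stats::rnorm(TT))

  g <- nuisance_surface(X, cfg$nonlinear_nuisance)
  if (stats::sd(g) > 0) g <- (g - mean(g)) / stats::sd(g) * cfg$noise_sd

  med_names <- names(cfg$mediator_paths)
  M <- matrix(0, n, length(med_names), dimnames = list(NULL, med_names))
  b_path <- numeric(length(med_names))
  for (m in seq_along(med_names)) {
    pa <- cfg$mediator_paths[[m]]
    hm <- 0.3 * rowMeans(X[, seq_len(min(2L, p)), drop = FALSE])
    M[, m] <- pa[["a"]] * D + hm + stats::rnorm(n, sd = 0.3)
    b_path[m] <- pa[["b"]]
  }

  y <- cfg$theta_true * D + g + drop(M %*% b_path) +
    alpha[city_id] + tau[match(year, years)] +
    .ETA_SD * eta[city_id] + stats::rnorm(n, sd = cfg$noise_sd)

  clip_fraction <- NA_real_
  if (cfg$index_scale) {
    y_idx <- 0.16 * exp(y)
    clip_fraction <- mean(y_idx > 1 | y_idx < 0)
    y <- pmin(pmax(y_idx, 0), 1)
  }

  panel <- data.frame(
    city_id = city_id, province_id = province_id[city_id], year = year,
    PHL = y, SCC = D, X, M,
    region = region[city_id], size = size[city_id],
    regulation = regulation[city_id], batch = batch[city_id],
    instrument_base = instrument_base[city_id],
    stringsAsFactors = FALSE)
  class(panel) <- c("panel_dataset", "data.frame")
  attr(panel, "dgp_config") <- cfg
  attr(panel, "true_effects") <- true_effects(cfg)
  attr(panel, "clip_fraction") <- clip_fraction
  validate_panel(panel)
  panel
}

#' Ground-truth effects implied by a DGP configuration
#'
#' @param cfg a \code{\link{dgp_config}}.
#' @return list with \code{theta} (direct effect), \code{indirect}
#'   (named vector of per-mediator products a*b) and \code{total}
#'   (theta plus the summed indirect effects).
#' @export
true_effects <- function(cfg) {
  validate_dgp_config(cfg)
  ind <- vapply(cfg$mediator_paths,
                function(m) unname(m[["a"]] * m[["b"]]), numeric(1))
  list(theta = cfg$theta_true, indirect = ind,
       total = cfg$theta_true + sum(ind))
}

#' Validate the structural invariants of a panel
#'
#' Checks that the panel is balanced (every city observed in every year
#' exactly once), that treatment is an absorbing state within each city,
#' and that the outcome is finite.
#'
#' @param panel a data.frame with at least \code{city_id, year, PHL, SCC}.
#' @return the panel, invisibly; errors describe the violated invariant.
#' @export
validate_panel <- function(panel) {
  need <- c("city_id", "year", "PHL", "SCC")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel misses columns: ", paste(miss, collapse = ", "))
  tab <- table(panel$city_id, panel$year)
  if (any(tab != 1L)) stop("panel is not balanced: some (city, year) cell is absent or duplicated")
  if (!all(panel$SCC %in% c(0L, 1L))) stop("treatment SCC must be binary 0/1")
  ord <- order(panel$city_id, panel$year)
  d <- panel$SCC[ord]; cid <- panel$city_id[ord]
  drop_back <- diff(d) < 0 & diff(cid) == 0
  if (any(drop_back)) stop("treatment is not an absorbing state within city")
  if (!all(is.finite(panel$PHL))) stop("outcome contains non-finite values")
  invisible(panel)
}

#' Raw indicator table underlying the composite health index
#'
#' Simulates the five indicators from which the entropy-weight index is
#' built: per-capita fiscal health expenditure, hospital beds per 10,000
#' people, doctors per 10,000 people, population survival rate (all
#' positive direction) and infectious-disease incidence (negative
#' direction).  All five are strictly monotone transforms of one latent
#' city-year health factor plus indicator noise, so the resulting
#' composite index tracks the latent factor.
#'
#' @param cfg a \code{\link{dgp_config}}; \code{indicator_noise_sd = 0}
#'   makes the indicators exact monotone transforms of the latent factor.
#' @return data.frame with \code{city_id, year}, the five indicator
#'   columns, and attributes \code{specs} (an \code{\link{indicator_specs}}
#'   table) and \code{latent} (the latent factor, for validation).
#' @export
generate_indicator_table <- function(cfg) {
  validate_dgp_config(cfg)
  N <- cfg$n_cities; TT <- cfg$n_years
  years <- cfg$start_year + seq_len(TT) - 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 104729L)  # independent stream from generate_panel

  n <- N * TT
  city_id <- rep(seq_len(N), each = TT)
  latent <- stats::rnorm(N)[city_id] * 0.8 + stats::rnorm(n) * 0.6
  s <- cfg$indicator_noise_sd
  noise <- function() stats::rnorm(n, sd = s)
  tab <- data.frame(
    city_id = city_id, year = rep(years, times = N),
    fiscal_health_exp = 800 * exp(0.8 * latent + noise()),
    beds_per_10k      = 45 * exp(0.5 * latent + noise()),
    doctors_per_10k   = 30 * exp(0.6 * latent + noise()),
    survival_rate     = 100 * stats::plogis(2.2 + 0.7 * latent + noise()),
    infectious_incidence = 50 * exp(-0.6 * latent + noise()))
  attr(tab, "specs") <- indicator_specs()
  attr(tab, "latent") <- latent
  tab
}

#' Direction specification of the default health-indicator set
#'
#' @return data.frame with columns \code{name} and \code{direction}
#'   (\code{"positive"} or \code{"negative"}); infectious-disease
#'   incidence is the only loss-type (negative) indicator.
#' @export
indicator_specs <- function() {
  data.frame(
    name = c("fiscal_health_exp", "beds_per_10k", "doctors_per_10k",
             "survival_rate", "infectious_incidence"),
    direction = c("positive", "positive", "positive", "positive", "negative"),
    stringsAsFactors = FALSE)
}

#' @export
print.panel_dataset <- function(x, ...) {
  cfg <- attr(x, "dgp_config")
  cat("<panel_dataset> ", length(unique(x$city_id)), " cities x ",
      length(unique(x$year)), " years (", nrow(x), " rows)\n", sep = "")
  cat("  treated city-years: ", sum(x$SCC), " (",
      round(100 * mean(x$SCC), 1), "%)\n", sep = "")
  if (!is.null(cfg))
    cat("  true theta: ", cfg$theta_true, ", total effect: ",
        round(attr(x, "true_effects")$total, 4), "\n", sep = "")
  invisible(x)
}
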