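#' Design-preparation settings
#'
#' Controls how a raw panel is turned into the high-dimensional control
#' design passed to the nuisance learners: within-city interpolation of
#' missing values, two-sided winsorization, quadratic expansion of the
#' controls, year/city fixed-effect dummies, province-specific linear
#' trends, and verbatim policy dummies.  Fixed effects are included as
#' one-hot features inside the control set (not pre-demeaned), treating
#' them as part of the high-dimensional nuisance the learners absorb.
#'
#' @param winsor_bounds optional length-2 numeric, e.g. \code{c(0.01, 0.99)}
#'   or \code{c(0.05, 0.95)}: empirical quantiles at which continuous
#'   variables are clipped.  \code{NULL} disables winsorization.
#' @param interpolate_missing fill gaps by within-city linear
#'   interpolation before building the design.
#' @param add_squares append the square of every control column.
#' @param fe_year,fe_city include one-hot year / city dummies (first
#'   level dropped as reference).
#' @param province_trend per-province linear trend columns
#'   \code{(year - first year) * 1(province)}.
#' @param policy_dummies names of binary columns to append verbatim
#'   (e.g. concurrent policy pilots).
#' @param exclude_from_winsor columns never winsorized; the treatment
#'   column is always excluded.
#' @return object of class \code{prep_config}.
#' @export
prep_config <- function(winsor_bounds = NULL,
                        interpolate_missing = TRUE,
                        add_squares = TRUE,
                        fe_year = TRUE,
                        fe_city = FALSE,
                        province_trend = FALSE,
                        policy_dummies = character(),
                        exclude_from_winsor = character()) {
  if (!is.null(winsor_bounds)) {
    stopifnot(length(winsor_bounds) == 2)
    if (!(winsor_bounds[1] > 0 && winsor_bounds[2] < 1 &&
          winsor_bounds[1] < winsor_bounds[2]))
      stop("winsor_bounds must satisfy 0 < lower < upper < 1")
  }
  structure(list(winsor_bounds = winsor_bounds,
                 interpolate_missing = isTRUE(interpolate_missing),
                 add_squares = isTRUE(add_squares),
                 fe_year = isTRUE(fe_year), fe_city = isTRUE(fe_city),
                 province_trend = isTRUE(province_trend),
                 policy_dummies = policy_dummies,
                 exclude_from_winsor = exclude_from_winsor),
            class = "prep_config")
}

#' Fill missing values by within-city linear interpolation
#'
#' Each city's series of a continuous column is linearly interpolated
#' over years; gaps at the start or end of a series are filled with the
#' nearest observed value (no extrapolation).  A column that is entirely
#' missing for some city cannot be filled and raises an error naming the
#' city and column.  A complete panel is returned unchanged.
#'
#' @param panel long panel data.frame with \code{city_id} and \code{year}.
#' @param cols columns to interpolate; default: all numeric columns with
#'   missing values.
#' @return the panel with gaps filled.
#' @export
interpolate_missing <- function(panel, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(panel, is.numeric, logical(1))
    cols <- names(panel)[num & vapply(panel, anyNA, logical(1))]
  }
  if (!length(cols)) return(panel)
  ord <- order(panel$city_id, panel$year)
  for (cl in cols) {
    x <- panel[[cl]][ord]
    cid <- panel$city_id[ord]
    for (g in split(seq_along(x), cid)) {
      xi <- x[g]
      if (!anyNA(xi)) next
      if (all(is.na(xi)))
        stop("column '", cl, "' entirely missing for city ", cid[g[1]])
      x[g] <- stats::approx(panel$year[ord][g][!is.na(xi)], xi[!is.na(xi)],
                            xout = panel$year[ord][g], rule = 2)$y
    }
    panel[[cl]][ord] <- x
  }
  panel
}

#' Two-sided winsorization of continuous panel columns
#'
#' Clips each included column to its pooled empirical quantiles
#' \code{[q_lo, q_hi]}.  Binary columns, identifiers, the year, and any
#' column named in \code{exclude} (the treatment is always excluded) are
#' left untouched.  Winsorization is idempotent at fixed bounds and never
#' creates values outside the observed range.
#'
#' @param panel long panel data.frame.
#' @param bounds length-2 quantile pair, e.g. \code{c(0.01, 0.99)}.
#' @param exclude additional column names to leave untouched.
#' @param cols columns to winsorize; default: all non-binary numeric
#'   columns except ids/year/excluded.
#' @return the winsorized panel.
#' @export
winsorize <- function(panel, bounds = c(0.01, 0.99),
                      exclude = character(), cols = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] < 1,
            bounds[1] < bounds[2])
  never <- union(c("city_id", "province_id", "year", "SCC"), exclude)
  if (is.null(cols)) {
    num <- names(panel)[vapply(panel, is.numeric, logical(1))]
    cols <- setdiff(num, never)
    cols <- cols[vapply(panel[cols], function(x)
      length(unique(x)) > 2L, logical(1))]   # skip binary dummies
  } else {
    bad <- cols[!vapply(panel[cols], is.numeric, logical(1))]
    if (length(bad)) stop("cannot winsorize non-numeric column(s): ",
                          paste(bad, collapse = ", "))
    cols <- setdiff(cols, never)
  }
  for (cl in cols) {
    # type-1 (order-statistic) quantiles make winsorization idempotent
    q <- stats::quantile(panel[[cl]], probs = bounds, na.rm = TRUE,
                         names = FALSE, type = 1)
    panel[[cl]] <- pmin(pmax(panel[[cl]], q[1]), q[2])
  }
  panel
}

#' Build the high-dimensional control design matrix
#'
#' Assembles, in order: control levels, their squares (optional), year
#' dummies, city dummies (reference levels dropped), province-by-trend
#' columns and verbatim policy dummies.  Column roles are recorded in the
#' \code{roles} attribute.  The output is a deterministic function of the
#' panel and the configuration.
#'
#' @param panel complete (no missing values) long panel.
#' @param cfg a \code{\link{prep_config}}.
#' @param controls names of the control columns; default: every column
#'   matching \code{^X[0-9]+$}.
#' @return numeric matrix with one row per panel row.
#' @export
build_design <- function(panel, cfg = prep_config(), controls = NULL) {
  if (is.null(controls)) controls <- grep("^X[0-9]+$", names(panel), value = TRUE)
  if (!length(controls)) stop("no control columns found")
  if (anyNA(panel[controls])) stop("panel has missing values; interpolate first")
  blocks <- list(); roles <- character()
  Xc <- as.matrix(panel[controls])
  blocks$controls <- Xc
  roles <- c(roles, rep("control", ncol(Xc)))
  if (cfg$add_squares) {
    sq <- Xc^2; colnames(sq) <- paste0(controls, "_sq")
    blocks$squares <- sq
    roles <- c(roles, rep("control_sq", ncol(sq)))
  }
  if (cfg$fe_year) {
    yrs <- sort(unique(panel$year))
    if (length(yrs) > 1) {
      yd <- outer(panel$year, yrs[-1], "==") * 1
      colnames(yd) <- paste0("year_", yrs[-1])
      blocks$fe_year <- yd
      roles <- c(roles, rep("fe_year", ncol(yd)))
    }
  }
  if (cfg$fe_city) {
    cids <- sort(unique(panel$city_id))
    if (length(cids) < 2) stop("fe_city requires at least two cities")
    cd <- outer(panel$city_id, cids[-1], "==") * 1
    colnames(cd) <- paste0("city_", cids[-1])
    blocks$fe_city <- cd
    roles <- c(roles, rep("fe_city", ncol(cd)))
  }
  if (cfg$province_trend) {
    if (!"province_id" %in% names(panel))
      stop("province_trend requires a province_id column")
    provs <- sort(unique(panel$province_id))
    tr <- panel$year - min(panel$year)
    pt <- outer(panel$province_id, provs, "==") * tr
    colnames(pt) <- paste0("prov_", provs, "_trend")
    blocks$province_trend <- pt
    roles <- c(roles, rep("province_trend", ncol(pt)))
  }
  if (length(cfg$policy_dummies)) {
    miss <- setdiff(cfg$policy_dummies, names(panel))
    if (length(miss)) stop("policy dummy column(s) not in panel: ",
                           paste(miss, collapse = ", "))
    pd <- as.matrix(panel[cfg$policy_dummies])
    blocks$policy <- pd
    roles <- c(roles, rep("policy", ncol(pd)))
  }
  out <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(out))) stop("duplicate design column names")
  attr(out, "roles") <- roles
  out
}

#' Apply the full preparation pipeline to a panel
#'
#' Convenience wrapper: interpolation (if enabled), then winsorization
#' (if bounds are set, always excluding the treatment column).
#'
#' @param panel long panel data.frame.
#' @param cfg a \code{\link{prep_config}}.
#' @return the prepared panel.
#' @export
prepare_panel <- function(panel, cfg = prep_config()) {
  if (cfg$interpolate_missing) panel <- interpolate_missing(panel)
  if (!is.null(cfg$winsor_bounds))
    panel <- winsorize(panel, cfg$winsor_bounds,
                       exclude = cfg$exclude_from_winsor)
  panel
}
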