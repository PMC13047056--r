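#' Min-max normalize direction-tagged indicators
#'
#' Positive-direction indicators are mapped by (x - min) / (max - min),
#' negative-direction (loss-type) indicators by (max - x) / (max - min),
#' so that larger always means better and every entry lies in [0, 1].
#' Normalization is computed over the full pooled set of rows, which
#' keeps the resulting index comparable across years.
#'
#' @param table data.frame or matrix of raw indicator columns (any
#'   non-indicator columns such as ids must be removed first).
#' @param specs data.frame with columns \code{name}, \code{direction}
#'   covering every column of \code{table}.
#' @return numeric matrix in [0, 1]; columns with zero range are set to
#'   0.5 and flagged in the \code{constant_cols} attribute (they carry
#'   no discriminating information and receive entropy weight 0).
#' @export
normalize_indicators <- function(table, specs) {
  Z <- as.matrix(table)
  if (!is.numeric(Z)) stop("indicator table must be numeric")
  if (nrow(Z) < 2) stop("need at least 2 rows to normalize")
  specs <- validate_indicator_specs(specs)
  miss <- setdiff(colnames(Z), specs$name)
  if (length(miss))
    stop("no direction spec for indicator(s): ", paste(miss, collapse = ", "))
  dir <- specs$direction[match(colnames(Z), specs$name)]
  rng <- apply(Z, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  span[const] <- 1
  N <- sweep(sweep(Z, 2, rng[1, ]), 2, span, "/")
  neg <- dir == "negative"
  N[, neg] <- 1 - N[, neg, drop = FALSE]
  N[, const] <- 0.5
  attr(N, "constant_cols") <- colnames(Z)[const]
  N
}

validate_indicator_specs <- function(specs) {
  specs <- as.data.frame(specs)
  if (!all(c("name", "direction") %in% names(specs)))
    stop("specs needs columns 'name' and 'direction'")
  if (anyDuplicated(specs$name)) stop("indicator names must be unique")
  if (!all(specs$direction %in% c("positive", "negative")))
    stop("direction must be 'positive' or 'negative'")
  specs
}

#' Entropy weights of normalized indicators
#'
#' Computes the information-entropy weight of each indicator from its
#' normalized column: shares p_ij = (z_ij + eps) / sum_i (z_ij + eps),
#' entropy e_j = -(1/ln n) sum_i p_ij ln p_ij, divergence d_j = 1 - e_j,
#' and weights w_j = d_j / sum_j d_j.  An indicator whose normalized
#' column is constant has a uniform share distribution, hence e_j = 1
#' and weight 0.  \code{eps} (default 1e-12) guards ln 0.
#'
#' @param normalized matrix in [0, 1] with at least 2 rows.
#' @param eps continuity constant added to every share numerator.
#' @return list with \code{weights} (non-negative, summing to 1) and
#'   \code{entropies} (per-indicator, in [0, 1] up to eps slack).
#' @export
entropy_weights <- function(normalized, eps = 1e-12) {
  Z <- as.matrix(normalized)
  if (nrow(Z) < 2) stop("need at least 2 rows")
  if (any(Z < -1e-9 | Z > 1 + 1e-9)) stop("normalized values must lie in [0, 1]")
  n <- nrow(Z)
  P <- sweep(Z + eps, 2, colSums(Z + eps), "/")
  e <- -colSums(P * log(P)) / log(n)
  d <- 1 - e
  d[apply(Z, 2, function(col) max(col) == min(col))] <- 0
  d <- pmax(d, 0)   # eps can push e marginally above 1
  if (sum(d) <= 0)
    stop("all indicator columns are constant: no information to weight")
  list(weights = d / sum(d), entropies = e)
}

#' Composite index by the entropy weight method
#'
#' Chains direction-aware min-max normalization, entropy weighting and
#' the weighted sum into a bounded composite index, returning every
#' intermediate for audit.  With \code{equal_weights = TRUE} the entropy
#' step is bypassed and all indicators get weight 1/m (debug mode).
#'
#' @inheritParams normalize_indicators
#' @param equal_weights use uniform instead of entropy weights.
#' @param eps passed to \code{\link{entropy_weights}}.
#' @return object of class \code{composite_index}: list with
#'   \code{index} (in [0, 1], one value per row), \code{weights},
#'   \code{entropies}, \code{normalized}, \code{specs}.
#' @export
composite_index <- function(table, specs, equal_weights = FALSE, eps = 1e-12) {
  N <- normalize_indicators(table, specs)
  if (equal_weights) {
    w <- rep(1 / ncol(N), ncol(N))
    ent <- rep(NA_real_, ncol(N))
  } else {
    ew <- entropy_weights(N, eps = eps)
    w <- ew$weights; ent <- ew$entropies
  }
  names(w) <- colnames(N)
  res <- list(index = as.numeric(N %*% w), weights = w, entropies = ent,
              normalized = N, specs = validate_indicator_specs(specs))
  class(res) <- "composite_index"
  res
}

#' @export
print.composite_index <- function(x, ...) {
  cat("<composite_index> ", length(x$index), " rows, ",
      length(x$weights), " indicators\n", sep = "")
  cat("  weights:\n")
  print(round(x$weights, 4))
  cat("  index: mean ", round(mean(x$index), 4),
      ", range [", round(min(x$index), 4), ", ",
      round(max(x$index), 4), "]\n", sep = "")
  invisible(x)
}
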