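#' Nitrogen digestibility index from an in vitro digestion pair
#'
#' Computes the fraction of foliar nitrogen that is available to a herbivore,
#' from paired measurements taken before and after an in vitro digestion:
#' \deqn{D_N = \frac{N_0 \, DM_0 - N_1 \, DM_1}{N_0 \, DM_0}}
#' where \eqn{N} is the nitrogen concentration in dry matter and \eqn{DM} the
#' dry-matter mass, subscript 0 denoting pre-digestion and 1 post-digestion.
#' A high index indicates a high proportion of available (non-tannin-bound)
#' nitrogen relative to total foliar nitrogen.
#'
#' Values below zero are possible when measurement noise makes the residual
#' nitrogen mass exceed the initial mass; these are returned as-is with a
#' warning rather than silently clipped, so the caller can inspect them.
#'
#' @param n0 pre-digestion nitrogen concentration (fraction of dry matter).
#' @param dm0 pre-digestion dry-matter mass (g); must be positive.
#' @param n1 post-digestion nitrogen concentration.
#' @param dm1 post-digestion dry-matter mass (g); must satisfy
#'   `0 <= dm1 <= dm0`.
#' @return Numeric vector of digestibility indices, normally in `[0, 1]`.
#' @examples
#' n_digestibility(n0 = 2, dm0 = 1, n1 = 1, dm1 = 0.5) # 0.75
#' @export
n_digestibility <- function(n0, dm0, n1, dm1) {
  stopifnot(is.numeric(n0), is.numeric(dm0), is.numeric(n1), is.numeric(dm1))
  if (any(dm0 <= 0)) stop("pre-digestion dry matter `dm0` must be positive")
  if (any(n0 <= 0)) stop("pre-digestion nitrogen `n0` must be positive")
  if (any(n1 < 0) || any(dm1 < 0)) stop("post-digestion measurements must be non-negative")
  if (any(dm1 > dm0)) stop("post-digestion dry matter exceeds pre-digestion dry matter")
  denom <- n0 * dm0
  if (any(denom == 0)) stop("undefined index: n0 * dm0 is zero")
  out <- (denom - n1 * dm1) / denom
  if (any(out < 0)) {
    warning(sum(out < 0), " digestibility value(s) below 0 (measurement noise?); not clipped")
  }
  out
}

#' Dry-matter digestibility from pre- and post-digestion masses
#'
#' Fraction of leaf dry matter lost during in vitro digestion,
#' \eqn{(DM_0 - DM_1)/DM_0}.
#'
#' @param dm0 pre-digestion dry-matter mass (g); positive.
#' @param dm1 post-digestion dry-matter mass (g); in `[0, dm0]`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' dm_digestibility(1, 0.3) # 0.7
#' @export
dm_digestibility <- function(dm0, dm1) {
  stopifnot(is.numeric(dm0), is.numeric(dm1))
  if (any(dm0 <= 0)) stop("`dm0` must be positive")
  if (any(dm1 < 0)) stop("`dm1` must be non-negative")
  if (any(dm1 > dm0)) stop("`dm1` exceeds `dm0`")
  (dm0 - dm1) / dm0
}

#' Depth-averaged soil element value
#'
#' Soil cores are taken at several depths (0-10, 20-30 and 50-60 cm in the
#' default sampling design); a site-level element value is the arithmetic mean
#' over the non-missing depths. The number of depths that contributed is
#' recorded in the `"n_depths"` attribute.
#'
#' @param values numeric vector of per-depth concentrations; `NA` allowed.
#' @return scalar mean with attribute `n_depths`.
#' @examples
#' depth_average(c(1, 2, 3)) # 2
#' depth_average(c(5, NA, NA)) # 5
#' @export
depth_average <- function(values) {
  stopifnot(is.numeric(values))
  keep <- !is.na(values)
  if (!any(keep)) stop("all depth values missing: cannot compute a site-level mean")
  out <- mean(values[keep])
  attr(out, "n_depths") <- sum(keep)
  out
}

#' Aggregate leaf-level damage proportions to a tree-level response
#'
#' The tree-level herbivory response is the arithmetic mean of the per-leaf
#' proportions of leaf area lost, clamped into the open interval
#' `(eps, 1 - eps)` so it is always inside the support of a beta likelihood.
#' Values far from the boundary are preserved bit-exactly.
#'
#' @param leaf_proportions numeric vector of per-leaf damage fractions in
#'   `[0, 1]`; at least one leaf required.
#' @param min_leaves warn when fewer than this many leaves are present
#'   (default 10; the field protocol targets 20 leaves per tree).
#' @param eps clamp width, default `1e-6`.
#' @return scalar tree-level damage fraction strictly inside `(0, 1)`.
#' @examples
#' tree_damage(c(0.1, 0.3)) # 0.2
#' @export
tree_damage <- function(leaf_proportions, min_leaves = 10, eps = 1e-6) {
  stopifnot(is.numeric(leaf_proportions))
  if (length(leaf_proportions) == 0) stop("no leaves supplied")
  if (anyNA(leaf_proportions)) stop("missing leaf proportions")
  if (any(leaf_proportions < 0) || any(leaf_proportions > 1)) {
    stop("leaf proportions must lie in [0, 1]")
  }
  if (length(leaf_proportions) < min_leaves) {
    warning("only ", length(leaf_proportions), " leaves (< ", min_leaves,
            "): tree-level damage may be imprecise")
  }
  min(max(mean(leaf_proportions), eps), 1 - eps)
}

#' Centre and scale columns of a table, with exact back-transformation
#'
#' Each requested column is centred on its mean and scaled to unit standard
#' deviation. Quadratic terms, where requested, are built as the square of
#' the *standardized* linear column and appended as `<column>_sq` — this keeps
#' linear and quadratic terms on comparable scales so that one weakly
#' informative prior is comparably vague across all of them.
#'
#' @param table a data.frame.
#' @param columns character vector of numeric columns to standardize in place.
#' @param quadratic subset of `columns` for which a squared column is appended.
#' @return an object of class `standardized_table`: a list with elements
#'   `table` (the transformed data.frame) and `scaling` (a data.frame with
#'   `column`, `center`, `scale` enabling exact inversion via
#'   [unstandardize_columns()]).
#' @examples
#' s <- standardize_columns(data.frame(x = c(1, 2, 3)), "x")
#' s$table$x # -1, 0, 1 up to the sd scaling
#' @export
standardize_columns <- function(table, columns, quadratic = character()) {
  stopifnot(is.data.frame(table), all(columns %in% names(table)),
            all(quadratic %in% columns))
  scaling <- data.frame(column = columns, center = NA_real_, scale = NA_real_,
                        stringsAsFactors = FALSE)
  for (k in seq_along(columns)) {
    x <- table[[columns[k]]]
    if (!is.numeric(x)) stop("column `", columns[k], "` is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("column `", columns[k], "` has zero variance")
    m <- mean(x)
    table[[columns[k]]] <- (x - m) / s
    scaling$center[k] <- m
    scaling$scale[k] <- s
  }
  for (col in quadratic) {
    table[[paste0(col, "_sq")]] <- table[[col]]^2
  }
  structure(list(table = table, scaling = scaling), class = "standardized_table")
}

#' Invert [standardize_columns()]
#'
#' @param x a `standardized_table`.
#' @return the original data.frame (squared helper columns dropped).
#' @export
unstandardize_columns <- function(x) {
  stopifnot(inherits(x, "standardized_table"))
  tab <- x$table
  tab <- tab[, !grepl("_sq$", names(tab)) | !sub("_sq$", "", names(tab)) %in% x$scaling$column,
             drop = FALSE]
  for (k in seq_len(nrow(x$scaling))) {
    col <- x$scaling$column[k]
    tab[[col]] <- tab[[col]] * x$scaling$scale[k] + x$scaling$center[k]
  }
  tab
}
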