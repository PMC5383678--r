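# Centred log-ratio transform for strictly positive compositions.

#' Coerce a composition input to a positive numeric matrix
#'
#' Accepts a numeric matrix or a data frame; a column named `area_id` (if
#' present) is moved to the row names. Errors name the first offending row
#' and element when non-positive values are found.
#'
#' @param x matrix or data.frame of concentrations (mg/kg), all > 0.
#' @return numeric matrix with the same rows/columns.
#' @keywords internal
as_composition_matrix <- function(x) {
  ids <- NULL
  if (is.data.frame(x)) {
    if ("area_id" %in% names(x)) {
      ids <- as.character(x$area_id)
      x <- x[, setdiff(names(x), "area_id"), drop = FALSE]
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("composition must be numeric")
  if (!is.null(ids)) rownames(x) <- ids
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    r <- bad[1, 1]; c <- bad[1, 2]
    rn <- if (!is.null(rownames(x))) rownames(x)[r] else r
    cn <- if (!is.null(colnames(x))) colnames(x)[c] else c
    stop(sprintf(
      "non-positive or non-finite concentration at row '%s', element '%s' (%d offending cells)",
      rn, cn, nrow(bad)))
  }
  x
}

#' Centred log-ratio (clr) transformation
#'
#' Maps each row of a composition `x = (x_1, ..., x_D)` to
#' `y_d = log(x_d / g(x))`, where `g(x)` is the row geometric mean. The
#' division by the geometric mean removes the closure effect of
#' concentrations that sum to an (almost) fixed total mass, at the price of
#' a singular covariance: every clr row sums to zero, so the clr covariance
#' matrix has rank at most `D - 1`.
#'
#' Computed in log space (`log(x_d) - mean(log(x))`) for numerical
#' stability. Zero or negative entries are an error naming the offending
#' row and element; positivity is the responsibility of the upstream
#' interpolation step (see [krige_composition()]).
#'
#' @param x matrix or data.frame of strictly positive concentrations, one
#'   row per location, one column per element. A column named `area_id` is
#'   carried to the row names.
#' @return numeric matrix of clr coordinates, same dimensions and
#'   dimnames as `x`; each row sums to zero (within 1e-10).
#' @seealso [clr_inverse()]
#' @examples
#' clr_transform(matrix(c(1, 1, 1, 1), nrow = 1))  # zero vector
#' @export
clr_transform <- function(x) {
  x <- as_composition_matrix(x)
  lx <- log(x)
  y <- lx - rowMeans(lx)
  y
}

#' Inverse of the clr transformation
#'
#' Maps zero-sum clr rows back to compositions: `x` proportional to
#' `exp(y)`, rescaled so each row sums to `total`. The round trip
#' `clr_transform(clr_inverse(y, total))` returns `y` for any `total > 0`
#' because clr is scale invariant.
#'
#' @param y matrix of clr coordinates (rows sum to ~0).
#' @param total positive row total of the reconstructed composition.
#' @return matrix of positive compositions with row sums `total`.
#' @export
clr_inverse <- function(y, total = 1) {
  if (is.data.frame(y)) y <- as.matrix(y)
  stopifnot(is.numeric(y), is.numeric(total), total > 0)
  x <- exp(y)
  x * (total / rowSums(x))
}
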