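#' Define a factor space for a coded experimental design
#'
#' A factor space records, for each process factor, its center and half-range
#' on the actual (engineering-unit) scale, and owns the transform between
#' actual units and the symmetric coded scale where the center maps to 0 and
#' center +/- half-range map to +/- 1.
#'
#' @param names Character vector of factor labels.
#' @param center Numeric vector of factor centers (actual units).
#' @param half_range Numeric vector of positive half-ranges (actual units).
#'
#' @return An object of class `factor_space` with fields `names`, `center`,
#'   `half_range`, `low` (= center - half_range) and `high`
#'   (= center + half_range).
#' @seealso [code_points()], [decode_points()], [sep_factor_space()]
#' @export
#' @examples
#' fs <- factor_space(c("temperature_C", "time_h"), c(60, 3), c(10, 1))
#' fs$low
factor_space <- function(names, center, half_range) {
  names <- as.character(names)
  center <- as.numeric(center)
  half_range <- as.numeric(half_range)
  k <- length(names)
  if (length(center) != k || length(half_range) != k)
    stop("`names`, `center` and `half_range` must have the same length")
  if (!all(is.finite(center)) || !all(is.finite(half_range)))
    stop("factor centers and half-ranges must be finite")
  if (any(half_range <= 0))
    stop("every half_range must be strictly positive")
  structure(
    list(names = names, center = center, half_range = half_range,
         low = center - half_range, high = center + half_range),
    class = "factor_space")
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Factor space (", length(x$names), " factors)\n", sep = "")
  print(data.frame(factor = x$names, low = x$low, center = x$center,
                   high = x$high), row.names = FALSE)
  invisible(x)
}

#' Factor space of the selenium-enriched rape protein extraction study
#'
#' Four alkaline-extraction factors: temperature (50--70 degC), time (2--4 h),
#' NaOH concentration (0.2--0.3 mol/L) and liquid-to-material ratio
#' (50--70 mL/g; the ratio X:1 mL/g is stored as the scalar X).
#'
#' @return A [factor_space()] with centers (60, 3, 0.25, 60) and half-ranges
#'   (10, 1, 0.05, 10).
#' @export
#' @examples
#' code_points(c(70, 4, 0.3, 70), sep_factor_space())
sep_factor_space <- function() {
  factor_space(
    names = c("temperature_C", "time_h", "alkali_mol_L", "ratio_mL_g"),
    center = c(60, 3, 0.25, 60),
    half_range = c(10, 1, 0.05, 10))
}

as_setting_matrix <- function(x, space) {
  k <- length(space$names)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k)
      stop("expected a length-", k, " point or a matrix with ", k, " columns")
    x <- matrix(as.numeric(x), nrow = 1)
  }
  x <- matrix(as.numeric(x), nrow = nrow(x))
  if (ncol(x) != k)
    stop("expected ", k, " columns (one per factor), got ", ncol(x))
  if (!all(is.finite(x))) stop("factor settings must be finite")
  colnames(x) <- space$names
  x
}

#' Convert between actual and coded factor settings
#'
#' `code_points()` maps actual settings to the coded scale,
#' `coded = (actual - center) / half_range`; `decode_points()` is its inverse.
#' Both accept a single point (numeric vector) or a matrix/data frame with one
#' row per point, and are exact inverses of each other.
#'
#' @param actual,coded A numeric vector of length `k` (one point) or an
#'   `n x k` matrix of settings.
#' @param space A [factor_space()].
#'
#' @return A numeric matrix of the same shape (a single point is returned as a
#'   1-row matrix) with columns named after the factors.
#' @export
#' @examples
#' code_points(c(62.5, 3, 0.25, 62.2), sep_factor_space())
code_points <- function(actual, space) {
  x <- as_setting_matrix(actual, space)
  sweep(sweep(x, 2, space$center, "-"), 2, space$half_range, "/")
}

#' @rdname code_points
#' @export
decode_points <- function(coded, space) {
  x <- as_setting_matrix(coded, space)
  sweep(sweep(x, 2, space$half_range, "*"), 2, space$center, "+")
}
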