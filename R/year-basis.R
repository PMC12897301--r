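#' Piecewise-linear calendar-year basis
#'
#' Represents a continuous piecewise-linear effect of diagnosis year on the
#' log hazard: an offset term `f0(y) = y - y0` plus one hinge term
#' `fk(y) = max(0, y - tau_k)` per joinpoint. Coefficients on this basis are
#' increments: the slope of segment `k` is the cumulative sum of the first
#' `k` coefficients, so the fitted year effect is automatically continuous
#' at each joinpoint.
#'
#' @param y0 reference (series start) year.
#' @param joinpoints integer calendar years, strictly increasing, interior
#'   to the series.
#' @param y_end optional last diagnosis year, used to validate that each
#'   segment (including the first and last) spans at least `min_segment`
#'   years.
#' @param min_segment minimum segment length in years (default 3).
#' @return a `year_basis` object.
#' @export
year_basis <- function(y0, joinpoints = integer(0), y_end = NULL,
                       min_segment = 3L) {
  joinpoints <- as.integer(joinpoints)
  if (is.unsorted(joinpoints, strictly = TRUE)) {
    stop("joinpoints must be strictly increasing")
  }
  if (length(joinpoints) > 0) {
    if (joinpoints[1] - y0 < min_segment) {
      stop("first joinpoint leaves fewer than ", min_segment,
           " years before it")
    }
    if (any(diff(joinpoints) < min_segment)) {
      stop("joinpoints closer than ", min_segment, " years")
    }
    if (!is.null(y_end) && y_end - joinpoints[length(joinpoints)] < min_segment) {
      stop("last joinpoint leaves fewer than ", min_segment, " years after it")
    }
  }
  structure(list(y0 = as.integer(y0), joinpoints = joinpoints),
            class = "year_basis")
}

#' Evaluate a year basis
#'
#' @param basis a [year_basis()].
#' @param year integer vector of calendar years.
#' @return numeric matrix, one row per year, columns `f0`, then one hinge
#'   column per joinpoint.
#' @export
year_basis_eval <- function(basis, year) {
  stopifnot(inherits(basis, "year_basis"))
  X <- cbind(f0 = year - basis$y0)
  for (tau in basis$joinpoints) {
    X <- cbind(X, pmax(0, year - tau))
  }
  if (length(basis$joinpoints) > 0) {
    colnames(X) <- c("f0", paste0("hinge_", basis$joinpoints))
  }
  X
}

#' Convert between per-segment slopes and hinge-basis coefficients
#'
#' Coefficients on the hinge basis are slope increments: the slope of
#' segment `k` equals the cumulative sum of the first `k` coefficients.
#' `slopes_to_coef()` maps per-segment slopes (length joinpoints + 1) to
#' basis coefficients; `coef_to_slopes()` is the inverse.
#'
#' @param slopes per-segment slopes of the log hazard per calendar year.
#' @return numeric vector of basis coefficients.
#' @export
slopes_to_coef <- function(slopes) {
  c(slopes[1], diff(slopes))
}

#' @rdname slopes_to_coef
#' @param beta hinge-basis coefficients.
#' @export
coef_to_slopes <- function(beta) {
  cumsum(beta)
}
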