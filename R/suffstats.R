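#' Sufficient statistics of a set of events
#'
#' Zero-mean-parameterised sufficient statistics `(n, sum, scatter)` with
#' `scatter` the raw second moment \eqn{\sum_i x_i x_i'}. All collapsed
#' predictive densities in the package are functions of these three
#' quantities, so points can be moved between clusters in O(d^2).
#'
#' @param x Optional numeric matrix (rows = events) or vector (one event)
#'   used to initialise the statistics; `NULL` gives empty statistics.
#' @param d Dimensionality, required when `x` is `NULL`.
#' @return An object of class `"aspire_suffstats"`.
#' @examples
#' s <- suffstats(matrix(c(1, 2), 1, 2))
#' s$scatter   # outer product [[1,2],[2,4]]
#' @export
suffstats <- function(x = NULL, d = NULL) {
  if (is.null(x)) {
    if (is.null(d)) stop("'d' is required for empty statistics")
    out <- list(n = 0L, sum = numeric(d), scatter = matrix(0, d, d))
  } else {
    if (is.vector(x)) x <- matrix(x, nrow = 1)
    x <- as.matrix(x)
    out <- list(n = nrow(x), sum = colSums(x), scatter = crossprod(x))
  }
  class(out) <- "aspire_suffstats"
  out
}

#' Add or remove one event from sufficient statistics
#'
#' @param stats An `"aspire_suffstats"` object.
#' @param x A numeric vector (one event).
#' @param direction `"add"` or `"remove"`. Removing an event that was
#'   previously added restores the original statistics up to floating-point
#'   round-off; removing from empty statistics is an error.
#' @return Updated `"aspire_suffstats"`.
#' @export
suffstats_update <- function(stats, x, direction = c("add", "remove")) {
  direction <- match.arg(direction)
  x <- as.numeric(x)
  if (length(x) != length(stats$sum))
    stop("event dimensionality does not match the statistics")
  sgn <- if (direction == "add") 1 else -1
  if (direction == "remove" && stats$n < 1L)
    stop("cannot remove an event from empty statistics")
  stats$n <- stats$n + sgn * 1L
  stats$sum <- stats$sum + sgn * x
  stats$scatter <- stats$scatter + sgn * tcrossprod(x)
  if (stats$n == 0L) {  # snap to exact zero so empty means empty
    stats$sum[] <- 0
    stats$scatter[] <- 0
  }
  stats
}

#' @export
print.aspire_suffstats <- function(x, ...) {
  cat("Sufficient statistics: n =", x$n, "\n")
  cat("  sum =", format(x$sum, digits = 4), "\n")
  invisible(x)
}

## Normalise "class-side data" arguments: a single suffstats object is one
## local cluster; a list is a list of local clusters; NULL is an empty class.
as_cluster_list <- function(cl) {
  if (is.null(cl)) return(list())
  if (inherits(cl, "aspire_suffstats")) return(list(cl))
  if (is.list(cl)) {
    ok <- all(vapply(cl, inherits, logical(1), "aspire_suffstats"))
    if (!ok) stop("class data must be 'aspire_suffstats' or a list of them")
    return(cl[vapply(cl, function(s) s$n > 0L, logical(1))])
  }
  stop("class data must be 'aspire_suffstats' or a list of them")
}
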