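# Local polynomial regression (LOESS) with tricube weights, computed by the
# exact ("direct") algorithm: at each evaluation point a weighted polynomial
# is fitted to the span-nearest neighbours. Implemented here rather than
# wrapped so that the neighbourhood, weighting and tie-break conventions are
# explicit; tests cross-check against an independently generated oracle
# table.

#' Local polynomial (LOESS) fit
#'
#' Fits `y` on `x` by locally weighted polynomial regression. At an
#' evaluation point `x0` the `q = floor(span * n)` nearest data points (by
#' `|x - x0|`, input order breaking ties) receive tricube weights
#' `(1 - (d/h)^3)^3`, where `h` is the `q`-th smallest distance (when
#' `span > 1`, the maximum distance inflated by `sqrt(span)`), and a
#' polynomial of the requested degree is fitted by weighted least squares.
#'
#' @param x,y Numeric vectors of equal length (>= `max(4, degree + 2)`).
#' @param span Smoothing fraction in (0, 1] (values > 1 widen the bandwidth
#'   beyond the data range). Default 2/3.
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param newx Optional evaluation points for the returned prediction.
#' @return List of class `loess_fit` with `fitted`, `residuals`, `predict`
#'   (a function of new x values), and the inputs.
#' @export
loess_fit <- function(x, y, span = 2 / 3, degree = 2L, newx = NULL) {
  stopifnot(length(x) == length(y), span > 0, degree %in% c(1L, 2L))
  n <- length(x)
  if (n < max(4L, degree + 2L))
    stop("too few points for a local fit", call. = FALSE)
  q <- floor(n * min(span, 1))
  if (q < degree + 1L)
    stop("span too small: local neighbourhood smaller than degree + 1",
         call. = FALSE)
  predict_at <- function(x0) {
    vapply(x0, function(p) {
      d <- abs(x - p)
      h <- sort(d, partial = q)[q]
      if (span > 1) h <- max(d) * sqrt(span)
      if (h <= 0) h <- .Machine$double.eps
      w <- (1 - pmin(d / h, 1)^3)^3
      use <- w > 0
      if (sum(use) < degree + 1L) {
        # all mass on ties at x0: weighted mean
        return(sum(w * y) / sum(w))
      }
      xu <- x[use] - p
      X <- cbind(1, xu)
      if (degree == 2L) X <- cbind(X, xu^2)
      fit <- lm.wfit(X, y[use], w[use])
      unname(fit$coefficients[1L])
    }, numeric(1))
  }
  fitted <- predict_at(x)
  out <- list(x = x, y = y, span = span, degree = degree,
              fitted = fitted, residuals = y - fitted,
              predict = predict_at)
  if (!is.null(newx)) out$predicted <- predict_at(newx)
  class(out) <- "loess_fit"
  out
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("Local %s fit: n = %d, span = %.3f, residual SD = %.4g\n",
              if (x$degree == 2L) "quadratic" else "linear",
              length(x$x), x$span, sd(x$residuals)))
  invisible(x)
}
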