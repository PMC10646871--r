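#' @describeIn EulerCurve-class jump points of the step function
#' @param object,x An \code{EulerCurve}.
#' @export
jumps <- function(object) object@jumps

#' @describeIn EulerCurve-class Euler characteristic values attained at
#'   (and after) each jump
#' @export
ecValues <- function(object) object@values

#' @export
setMethod("length", "EulerCurve", function(x) length(x@jumps))

setMethod("show", "EulerCurve", function(object) {
  n <- length(object@jumps)
  cat(sprintf("EulerCurve with %d jump(s)\n", n))
  if (n) {
    k <- min(6L, n)
    cat("  jumps:  ", paste(signif(object@jumps[seq_len(k)], 6), collapse = ", "),
        if (n > k) ", ..." else "", "\n", sep = "")
    cat("  values: ", paste(object@values[seq_len(k)], collapse = ", "),
        if (n > k) ", ..." else "", "\n", sep = "")
    cat(sprintf("  final Euler characteristic: %g\n", object@values[n]))
  }
  invisible(NULL)
})

#' Evaluate an Euler characteristic curve
#'
#' Returns \eqn{\chi(K_t)}: the value at the largest jump point
#' \code{<= t} (the curve is right-continuous, since the sublevel complex
#' \eqn{K_t} contains every cell with filtration \code{<= t}), and 0 for
#' \code{t} before the first jump.  Lookup is a binary search
#' (\code{findInterval}), sub-linear in the number of jumps.
#'
#' @param curve An [EulerCurve-class].
#' @param t Numeric vector of filtration values.
#' @return Integer-valued numeric vector, one entry per element of \code{t}.
#' @examples
#' cv <- buildCurve(contributions(c(0, 1), c(3, -2)))
#' ecAt(cv, c(-1, 0, 0.5, 1, 2))
#' @export
ecAt <- function(curve, t) {
  stopifnot(is(curve, "EulerCurve"))
  idx <- findInterval(t, curve@jumps)
  out <- numeric(length(t))
  hit <- idx > 0
  out[hit] <- curve@values[idx[hit]]
  out
}

#' Convert a curve back to its contribution list
#'
#' @param curve An [EulerCurve-class].
#' @return Contribution data.frame with columns \code{f1, delta}.
#' @export
curveContributions <- function(curve) {
  stopifnot(is(curve, "EulerCurve"))
  v <- curve@values
  contributions(curve@jumps, if (length(v)) diff(c(0, v)) else numeric(0))
}

#' Plot an Euler characteristic curve
#'
#' Draws the right-continuous step function, extending it flat after the
#' last jump.
#'
#' @param x An [EulerCurve-class].
#' @param y Ignored.
#' @param xlab,ylab,... Passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "EulerCurve", y = "missing"),
  function(x, y, xlab = "filtration", ylab = "Euler characteristic", ...) {
    if (!length(x@jumps)) {
      graphics::plot(0, 0, type = "n", xlab = xlab, ylab = ylab, ...)
      return(invisible(NULL))
    }
    pad <- diff(range(x@jumps))
    if (pad == 0) pad <- 1
    xs <- c(x@jumps, max(x@jumps) + 0.1 * pad)
    graphics::plot(stats::stepfun(x@jumps, c(0, x@values)),
                   xlim = range(xs), do.points = FALSE,
                   xlab = xlab, ylab = ylab, main = "", ...)
    invisible(NULL)
  })
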