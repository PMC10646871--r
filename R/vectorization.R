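# Fixed-length vector / tensor summaries of curves and profiles for
# machine-learning pipelines.

#' Vectorize an Euler characteristic curve
#'
#' Samples the curve at \code{N} evenly spaced points between 0 and
#' \code{fMax} (endpoints included), at resolution
#' \code{Delta = fMax / (N - 1)}:
#' \code{c(EC(0), EC(Delta), ..., EC(fMax))}.  Sampling starts at 0 even
#' if the curve's first jump is negative (shift filtrations first for
#' negative-coordinate use cases), and each sample is the right-continuous
#' value (a jump at exactly \code{i * Delta} is included).
#'
#' @param curve An [EulerCurve-class].
#' @param fMax Positive upper end of the sampling range.
#' @param N Number of samples (>= 2).
#' @return List with \code{samples} (numeric length \code{N}),
#'   \code{fMax} and \code{delta} (the resolution).
#' @export
vectorizeCurve <- function(curve, fMax, N) {
  stopifnot(is(curve, "EulerCurve"), fMax > 0)
  if (N < 2) stop("N must be at least 2")
  ts <- seq(0, fMax, length.out = N)
  list(samples = ecAt(curve, ts), fMax = fMax, delta = fMax / (N - 1))
}

#' Reconstruction-error bound for curve vectorization
#'
#' Evaluates \eqn{\Delta (|K|/2 + F)} with
#' \eqn{F = \sum_i |EC(i\Delta) - EC((i+1)\Delta)|}, the sum of absolute
#' differences between consecutive samples.  The L1 distance between the
#' curve and (the step function of) its vectorization is bounded by this
#' quantity: jumps across a sampling interval cost at most the
#' sample-difference rectangle, and excursions that return to the same
#' sample value involve paired cells, at most \code{|K|/2} of them.
#' No analogous bound holds for profile vectorizations, where unseen
#' paired contributions can extend arbitrarily far.
#'
#' @param vec Result of [vectorizeCurve()].
#' @param cellCount Total number of cells \code{|K|} of the filtered
#'   complex behind the curve.
#' @return The bound (non-negative).
#' @export
vectorizationBound <- function(vec, cellCount) {
  stopifnot(cellCount >= 0)
  F <- sum(abs(diff(vec$samples)))
  vec$delta * (cellCount / 2 + F)
}

#' Step-function curve of a vectorization
#'
#' The vectorized curve reinterpreted as a step function: the sampled
#' value at \code{i * Delta} extends until the next sample point.  Useful
#' for measuring the reconstruction error with [distanceCurves()].
#'
#' @param vec Result of [vectorizeCurve()].
#' @return An [EulerCurve-class] with jumps at the sampling points.
#' @export
vectorizationToCurve <- function(vec) {
  ts <- seq(0, vec$fMax, length.out = length(vec$samples))
  v <- vec$samples
  keep <- c(TRUE, diff(v) != 0)
  new("EulerCurve", jumps = ts[keep], values = v[keep])
}

#' Vectorize an Euler characteristic profile
#'
#' Samples \code{ecpAt} on the inclusive grid
#' \code{seq(0, maxima[i], length.out = Ns[i])} per axis, returning an
#' n-dimensional integer tensor (row-major flattening is
#' \code{as.vector(aperm(tensor))}).
#'
#' @param profile An [EulerProfile-class].
#' @param maxima Per-axis sampling maxima.
#' @param Ns Per-axis sample counts (all >= 2).
#' @return List with \code{tensor} (array of dim \code{Ns}),
#'   \code{maxima} and \code{deltas} (per-axis resolutions).
#' @export
vectorizeProfile <- function(profile, maxima, Ns) {
  stopifnot(is(profile, "EulerProfile"))
  n <- ncol(profile@locations)
  if (length(maxima) != n || length(Ns) != n)
    stop(sprintf("maxima and Ns must have length %d", n))
  if (any(Ns < 2)) stop("all Ns must be at least 2")
  axes <- lapply(seq_len(n), function(ax)
    seq(0, maxima[ax], length.out = Ns[ax]))
  # one cumulative pass over an auxiliary grid instead of N^n ecpAt calls
  loc <- profile@locations
  delta <- profile@deltas
  dims <- as.integer(Ns)
  grid <- numeric(prod(dims))
  if (length(delta)) {
    idx <- vapply(seq_len(n), function(ax) {
      # contribution at location l is visible from the first sample >= l
      i <- findInterval(loc[, ax], axes[[ax]], left.open = TRUE) + 1L
      i
    }, integer(nrow(loc)))
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = n)
    ok <- rowSums(idx <= rep(dims, each = nrow(idx))) == n &
      rowSums(loc <= rep(vapply(axes, max, 0), each = nrow(loc))) == n
    idx <- idx[ok, , drop = FALSE]
    dlt <- delta[ok]
    if (nrow(idx)) {
      lin <- as.numeric(idx[, 1])
      if (n > 1) for (ax in 2:n)
        lin <- lin + (idx[, ax] - 1) * prod(dims[seq_len(ax - 1)])
      agg <- rowsum(dlt, lin)
      grid[as.numeric(rownames(agg))] <- agg
    }
    for (ax in seq_len(n)) grid <- .axisCumsum(grid, dims, ax)
  }
  list(tensor = array(grid, dim = dims), maxima = maxima,
       deltas = maxima / (Ns - 1))
}
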