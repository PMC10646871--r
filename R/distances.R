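# L1 distances between Euler characteristic curves and between truncated
# Euler characteristic profiles.

#' L1 distance between two Euler characteristic curves
#'
#' Computes \eqn{\int |ECC_1(t) - ECC_2(t)| dt} by merging the two
#' contribution lists (with the signs of the second flipped) in filtration
#' order and summing segment widths times the absolute running Euler
#' characteristic of the difference -- linear time in the list sizes.
#' Integration starts at the smallest merged jump (both curves are 0
#' before their first jumps).  If the curves do not eventually coincide,
#' the integral diverges; either supply \code{upper} to truncate it or an
#' error is raised.
#'
#' @param a,b [EulerCurve-class] objects.
#' @param upper Optional upper integration bound.
#' @return Non-negative distance.
#' @examples
#' a <- buildCurve(contributions(0, 1))
#' b <- buildCurve(contributions(0, 0))
#' distanceCurves(a, b, upper = 2)   # unit-height rectangle: 2
#' @export
distanceCurves <- function(a, b, upper = NULL) {
  stopifnot(is(a, "EulerCurve"), is(b, "EulerCurve"))
  ca <- curveContributions(a)
  cb <- curveContributions(b)
  f <- c(ca$f1, cb$f1)
  delta <- c(ca$delta, -cb$delta)
  if (!length(f)) return(0)
  if (is.null(upper) && sum(delta) != 0)
    stop("curves do not eventually coincide, so the L1 distance is unbounded; supply 'upper'")
  ord <- order(f)
  f <- f[ord]
  running <- cumsum(delta[ord])
  if (is.null(upper)) {
    widths <- diff(f)
    sum(widths * abs(running[-length(running)]))
  } else {
    keep <- f < upper
    f <- f[keep]
    running <- running[keep]
    if (!length(f)) return(0)
    widths <- diff(c(f, upper))
    sum(widths * abs(running))
  }
}

# cumulative sum along one axis of an array stored as a flat vector,
# vectorized across the remaining axes (loops only over the axis length)
.axisCumsum <- function(x, dims, axis) {
  m <- dims[axis]
  if (m <= 1) return(x)
  stride <- prod(dims[seq_len(axis - 1)])
  block <- stride * m
  nBlocks <- length(x) %/% block
  base <- as.vector(outer(seq_len(stride),
                          (seq_len(nBlocks) - 1) * block, `+`))
  for (l in seq_len(m - 1)) {
    idx <- base + l * stride
    x[idx] <- x[idx] + x[idx - stride]
  }
  x
}

#' L1 distance between two Euler characteristic profiles
#'
#' Computes \eqn{\int |ECP_1(v) - ECP_2(v)| dv} over the truncation box.
#' The merged, sign-flipped contribution lists induce an irregular grid
#' whose per-axis breakpoints are the distinct contribution coordinates;
#' inside each cuboid the Euler characteristic of the difference is
#' constant and equal to its value at the lower corner (obtained by
#' cumulative sums of the deltas along every axis).  The distance is the
#' sum of \code{|EC| * volume} over the cuboids, integrating from the
#' smallest breakpoint per axis (the difference is 0 below it) up to the
#' truncation.  Truncation is mandatory: without it cuboids have
#' infinite volume.
#'
#' @param a,b [EulerProfile-class] objects with the same arity.
#' @param truncation Per-axis upper bound \code{f_inf}; defaults to the
#'   truncation stored in the profiles when both agree.
#' @return Non-negative distance.
#' @export
distanceProfiles <- function(a, b, truncation = NULL) {
  stopifnot(is(a, "EulerProfile"), is(b, "EulerProfile"))
  n <- ncol(a@locations)
  if (ncol(b@locations) != n)
    stop("profiles have different numbers of parameters")
  if (is.null(truncation)) {
    ta <- a@truncation; tb <- b@truncation
    if (!is.null(ta) && !is.null(tb) && isTRUE(all(ta == tb))) truncation <- ta
    else if (!is.null(ta) && is.null(tb)) truncation <- ta
    else if (is.null(ta) && !is.null(tb)) truncation <- tb
  }
  if (is.null(truncation))
    stop("profile distances need a truncation (cuboids would have infinite volume)")
  if (length(truncation) != n)
    stop("truncation length must match the number of parameters")
  loc <- rbind(a@locations, b@locations)
  delta <- c(a@deltas, -b@deltas)
  inside <- rowSums(loc < rep(truncation, each = nrow(loc))) == n
  loc <- loc[inside, , drop = FALSE]
  delta <- delta[inside]
  if (!nrow(loc)) return(0)
  breaks <- lapply(seq_len(n), function(ax) sort(unique(loc[, ax])))
  dims <- vapply(breaks, length, 0L)
  idx <- vapply(seq_len(n), function(ax) match(loc[, ax], breaks[[ax]]),
                integer(nrow(loc)))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = n)
  lin <- as.numeric(idx[, 1])
  if (n > 1) for (ax in 2:n)
    lin <- lin + (idx[, ax] - 1) * prod(dims[seq_len(ax - 1)])
  grid <- numeric(prod(dims))
  agg <- rowsum(delta, lin)
  grid[as.numeric(rownames(agg))] <- agg
  for (ax in seq_len(n)) grid <- .axisCumsum(grid, dims, ax)
  grid <- abs(grid)
  # weight by cuboid volumes: per-axis widths up to the truncation
  for (ax in seq_len(n)) {
    w <- diff(c(breaks[[ax]], truncation[ax]))
    stride <- prod(dims[seq_len(ax - 1)])
    grid <- grid * w[(((seq_along(grid) - 1) %/% stride) %% dims[ax]) + 1]
  }
  sum(grid)
}
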