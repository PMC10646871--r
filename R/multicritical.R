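# Multicritical filtrations: a cell may enter an n-parameter filtration
# at several pairwise incomparable points p_1..p_k.  Its contribution to
# the profile must equal (-1)^dim on the union of the upward cones above
# the p_i and 0 elsewhere, without double counting where the cones
# overlap; the correcting deltas live on joins (coordinate-wise maxima)
# of subsets of the entry points.

#' Coordinate-wise join of filtration points
#'
#' \code{joinPoints(p, q)} is the coordinate-wise maximum
#' \eqn{p \vee q}; the upward cone above it is the intersection of the
#' cones above \code{p} and \code{q}.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Numeric vector \code{pmax(p, q)}.
#' @examples
#' joinPoints(c(0, 1), c(1, 0))
#' @export
joinPoints <- function(p, q) {
  if (length(p) != length(q))
    stop(sprintf("arity mismatch: %d vs %d", length(p), length(q)))
  pmax(p, q)
}

.comparable <- function(p, q) all(p <= q) || all(q <= p)

#' Contributions of a multicritical cell
#'
#' Given the pairwise incomparable entry points of a cell of dimension
#' \code{dim}, returns a finite contribution list whose accumulated delta
#' at every point \code{x} equals \code{(-1)^dim} if \code{x} dominates
#' some entry point and 0 otherwise.  Implemented by iterative
#' correction: the candidate support (joins of subsets of entry points)
#' is scanned in a linear extension of the product order, and at each
#' candidate the delta needed to restore the target indicator is added.
#' Comparable entry points are rejected rather than silently minimized,
#' so callers surface filtration bugs.
#'
#' @param entryPoints Numeric matrix, one pairwise-incomparable entry
#'   point per row (a single point may be given as a vector).
#' @param dim Non-negative integer dimension of the cell.
#' @return Contribution data.frame supported on joins of subsets of the
#'   entry points.
#' @examples
#' multicriticalContributions(rbind(c(0, 1), c(1, 0)), dim = 0)
#' @export
multicriticalContributions <- function(entryPoints, dim = 0L) {
  if (is.null(base::dim(entryPoints)))
    entryPoints <- matrix(entryPoints, nrow = 1)
  entryPoints <- as.matrix(entryPoints)
  stopifnot(dim >= 0, nrow(entryPoints) >= 1)
  k <- nrow(entryPoints)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    if (.comparable(entryPoints[i, ], entryPoints[j, ]))
      stop("entry points must be pairwise incomparable; reduce to the minimal antichain first")
  }
  # closure of the entry points under pairwise join = joins of all subsets
  cand <- unique(entryPoints)
  repeat {
    extra <- list()
    for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) if (i < j) {
      jn <- joinPoints(cand[i, ], cand[j, ])
      extra[[length(extra) + 1]] <- jn
    }
    grown <- unique(rbind(cand, do.call(rbind, extra)))
    if (nrow(grown) == nrow(cand)) break
    cand <- grown
  }
  # linear extension of the product order: x < y coordinate-wise implies
  # sum(x) < sum(y), so sorting by coordinate sum (ties broken
  # lexicographically) scans every point after everything below it
  ord <- do.call(order, c(list(rowSums(cand)), asplit(cand, 2)))
  cand <- cand[ord, , drop = FALSE]
  locs <- list(); deltas <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    q <- cand[i, ]
    acc <- 0
    if (length(deltas)) {
      below <- vapply(seq_along(deltas),
                      function(r) all(locs[[r]] <= q), NA)
      acc <- sum(deltas[below])
    }
    target <- as.numeric(any(apply(entryPoints, 1, function(p) all(p <= q))))
    if (acc != target) {
      locs[[length(locs) + 1]] <- q
      deltas <- c(deltas, target - acc)
    }
  }
  contributions(do.call(rbind, locs), deltas * (-1)^dim)
}
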