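# Empirical verification machinery for the stability results: Betti
# curves from persistence diagrams, an exact brute-force 1-Wasserstein
# distance, and the curve / profile perturbation bound checks.

#' Betti curve of a persistence diagram
#'
#' The step function \eqn{\beta_k(D, t) = \sum_{(b,d)} I_{[b,d)}(t)}: each
#' diagram point switches on at its birth and off at its death (the bar
#' is half-open, so at \code{t = death} the class is gone).  Points with
#' infinite death never switch off.
#'
#' @param diagram A [PersistenceDiagram-class].
#' @return An [EulerCurve-class] holding the (non-negative) Betti counts.
#' @examples
#' ecValues(bettiCurve(PersistenceDiagram(c(0, 1), c(2, 3))))
#' @export
bettiCurve <- function(diagram) {
  stopifnot(is(diagram, "PersistenceDiagram"))
  b <- diagram@births
  d <- diagram@deaths
  finite <- is.finite(d)
  buildCurve(contributions(c(b, d[finite]),
                           c(rep(1, length(b)), rep(-1, sum(finite)))))
}

.diagonalCost <- function(b, d) (d - b) / 2

#' Exact 1-Wasserstein distance between small persistence diagrams
#'
#' Minimizes, over all matchings between the two diagrams (including
#' matches to the nearest diagonal projection
#' \code{((b+d)/2, (b+d)/2)}), the sum of l-infinity displacement costs.
#' The search is exhaustive -- an exact assignment dynamic program over
#' subsets of one diagram -- and is restricted to diagrams with at most
#' \code{maxPoints} off-diagonal points.
#'
#' @param a,b [PersistenceDiagram-class] objects.
#' @param maxPoints Brute-force size guard (default 8).
#' @return Non-negative distance.
#' @examples
#' wasserstein1(PersistenceDiagram(0, 2), PersistenceDiagram())
#' @export
wasserstein1 <- function(a, b, maxPoints = 8L) {
  stopifnot(is(a, "PersistenceDiagram"), is(b, "PersistenceDiagram"))
  na <- length(a@births); nb <- length(b@births)
  if (na > maxPoints || nb > maxPoints)
    stop(sprintf(
      "diagrams with more than %d points are beyond the exhaustive matcher; subsample first",
      maxPoints))
  if (nb > na) return(wasserstein1(b, a, maxPoints))
  diagA <- .diagonalCost(a@births, a@deaths)
  diagB <- .diagonalCost(b@births, b@deaths)
  if (nb == 0) return(sum(diagA))
  cost <- outer(seq_len(na), seq_len(nb), function(i, j)
    pmax(abs(a@births[i] - b@births[j]), abs(a@deaths[i] - b@deaths[j])))
  cost <- matrix(cost, na, nb)
  # f[mask + 1]: minimal cost of matching points i..na of A against the
  # unused points of B (mask = set of already-used B points); unused B
  # points left at the end go to the diagonal
  nMask <- bitwShiftL(1L, nb)
  maskBits <- lapply(seq_len(nMask) - 1L,
                     function(m) which(bitwAnd(m, bitwShiftL(1L, seq_len(nb) - 1L)) > 0))
  f <- vapply(maskBits, function(used) sum(diagB[setdiff(seq_len(nb), used)]), 0)
  for (i in rev(seq_len(na))) {
    g <- numeric(nMask)
    for (m in seq_len(nMask)) {
      used <- maskBits[[m]]
      best <- diagA[i] + f[m]
      for (j in setdiff(seq_len(nb), used)) {
        cand <- cost[i, j] + f[m + bitwShiftL(1L, j - 1L)]
        if (cand < best) best <- cand
      }
      g[m] <- best
    }
    f <- g
  }
  f[1]
}

#' Empirical Betti-curve stability check
#'
#' Computes the two sides of the stability inequality
#' \eqn{\|\beta(C) - \beta(D)\|_1 \le 2 W_1(C, D)}: the L1 distance
#' between the Betti curves and twice the 1-Wasserstein distance between
#' the diagrams.
#'
#' @param a,b [PersistenceDiagram-class] objects within the brute-force
#'   regime of [wasserstein1()].
#' @return Named list with \code{lhs} and \code{rhs}.
#' @export
checkBettiStability <- function(a, b) {
  lhs <- distanceCurves(bettiCurve(a), bettiCurve(b))
  rhs <- 2 * wasserstein1(a, b)
  list(lhs = lhs, rhs = rhs)
}

#' Empirical profile perturbation bound check
#'
#' Shifts every contribution of \code{profile} by an independent uniform
#' amount of at most \code{epsilon} per coordinate (an l-infinity
#' perturbation of the underlying filtration), clamps the locations to
#' \code{[0, fInf]}, and compares the L1 profile distance over the
#' truncation box \code{[0, fInf]^n} (the \code{lhs}) against the bound
#' \code{cellCount * n * epsilon^(n-1) * fInf} (the \code{rhs}).
#'
#' @param profile An [EulerProfile-class] whose contributions are raw
#'   cells (one \code{+-1} delta per cell).
#' @param epsilon Maximal per-coordinate shift (>= 0).
#' @param cellCount Number of cells \code{|K|} of the complex.
#' @param fInf Truncation value applied to every axis.
#' @return Named list with \code{lhs}, \code{rhs} and the perturbed
#'   profile.
#' @export
checkEcpPerturbation <- function(profile, epsilon, cellCount, fInf) {
  stopifnot(is(profile, "EulerProfile"), epsilon >= 0, fInf > 0)
  n <- ncol(profile@locations)
  loc <- profile@locations
  shift <- matrix(stats::runif(length(loc), -epsilon, epsilon), nrow(loc), n)
  pert <- pmin(pmax(loc + shift, 0), fInf)
  perturbed <- newEulerProfile(contributions(pert, profile@deltas))
  lhs <- distanceProfiles(profile, perturbed, truncation = rep(fInf, n))
  rhs <- cellCount * n * epsilon^(n - 1) * fInf
  list(lhs = lhs, rhs = rhs, perturbed = perturbed)
}
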