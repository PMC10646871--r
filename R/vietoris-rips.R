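# Distributed ECC/ECP contributions for Vietoris-Rips flag complexes.
# Each vertex i owns the simplices whose minimal vertex (in the chosen
# ordering) is i; they are enumerated breadth-first inside the local graph
# of i's subsequent epsilon-neighbors, so every simplex is generated
# exactly once and the per-vertex tasks are independent.

.asPointMatrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  storage.mode(points) <- "double"
  points
}

.euclidean <- function(a, b) sqrt(sum((a - b)^2))

#' Order the vertices of a pointcloud
#'
#' The \code{"ascending_degree"} strategy sorts vertices by their number
#' of neighbors within \code{threshold} (ties broken by original index).
#' Putting high-degree hubs last makes the per-vertex local simplex trees
#' more evenly sized, which balances parallel work; the aggregated
#' contributions are invariant to the ordering.
#'
#' @param points Numeric matrix, one point per row.
#' @param threshold Neighborhood radius (simplex diameter bound), >= 0.
#' @param strategy \code{"given"} (identity order) or
#'   \code{"ascending_degree"}.
#' @param metric Distance function of two points (default Euclidean);
#'   must be symmetric and non-negative.
#' @return Integer permutation of \code{1:nrow(points)}.
#' @export
orderVertices <- function(points, threshold,
                          strategy = c("given", "ascending_degree"),
                          metric = NULL) {
  strategy <- match.arg(strategy)
  points <- .asPointMatrix(points)
  n <- nrow(points)
  if (strategy == "given" || n == 0) return(seq_len(n))
  D <- .distMatrix(points, metric)
  degree <- rowSums(D <= threshold) - 1
  order(degree, seq_len(n))
}

.distMatrix <- function(points, metric = NULL) {
  n <- nrow(points)
  if (is.null(metric)) {
    D <- as.matrix(stats::dist(points))
    dimnames(D) <- NULL
    return(D)
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    D[i, j] <- D[j, i] <- metric(points[i, ], points[j, ])
  }
  D
}

#' Local graph of subsequent neighbors
#'
#' The unit of parallel work: vertex \code{i} (position in
#' \code{ordering}), the later-ordered points within \code{threshold} of
#' it, and all their pairwise distances.
#'
#' @inheritParams orderVertices
#' @param ordering Integer permutation from [orderVertices()].
#' @param i Position of the center vertex in \code{ordering}.
#' @return List with \code{center} (original index), \code{neighbors}
#'   (original indices, ordered as in \code{ordering}), and \code{dist}
#'   (square distance matrix over \code{c(center, neighbors)}).
#' @export
buildLocalGraph <- function(points, ordering, i, threshold, metric = NULL) {
  points <- .asPointMatrix(points)
  stopifnot(i >= 1, i <= length(ordering))
  center <- ordering[i]
  later <- ordering[seq_along(ordering) > i]
  if (length(later)) {
    dc <- if (is.null(metric)) {
      sqrt(colSums((t(points[later, , drop = FALSE]) - points[center, ])^2))
    } else {
      vapply(later, function(j) metric(points[center, ], points[j, ]), 0)
    }
    nbrs <- later[dc <= threshold]
  } else nbrs <- integer(0)
  verts <- c(center, nbrs)
  list(center = center, neighbors = nbrs,
       dist = .distMatrix(points[verts, , drop = FALSE], metric))
}

# Breadth-first expansion of the simplex tree rooted at the local graph's
# center (one level per dimension).  Each simplex is stored as its local
# vertex positions, its filtration (diameter so far) and its extendable
# set: the common subsequent neighbors of all its vertices.  Optionally
# carries per-vertex m-tuples extended by `rule` for multiparameter
# filtrations; the default rule is the coordinate-wise maximum.
.localContribs <- function(g, threshold = Inf, vertexValues = NULL,
                           rule = NULL) {
  D <- g$dist
  k <- length(g$neighbors)
  multi <- !is.null(vertexValues)
  if (multi && is.null(rule)) rule <- function(parent, vertex) pmax(parent, vertex)
  # subsequent adjacency inside the local graph (positions 2..k+1)
  subs <- vector("list", k + 1)
  for (v in seq_len(k + 1))
    subs[[v]] <- which(D[v, ] <= threshold & seq_len(k + 1) > v)
  locs <- list(); deltas <- list(); li <- 0
  rootVal <- if (multi) vertexValues[1, ] else NULL
  level <- list(list(verts = 1L, filt = 0, ext = subs[[1]], val = rootVal))
  li <- li + 1
  locs[[li]] <- if (multi) c(0, rootVal) else 0
  deltas[[li]] <- 1
  sign <- 1
  while (length(level)) {
    sign <- -sign
    nxt <- vector("list", sum(vapply(level, function(s) length(s$ext), 0L)))
    ni <- 0
    for (s in level) {
      for (v in s$ext) {
        filt <- max(s$filt, D[v, s$verts])
        ext <- intersect(s$ext[s$ext > v], subs[[v]])
        val <- if (multi) {
          nv <- rule(s$val, vertexValues[v, ])
          if (any(nv < s$val) || (multi && any(nv < vertexValues[v, ])))
            stop("invalid filtration: extension rule is not monotone")
          nv
        } else NULL
        ni <- ni + 1
        nxt[[ni]] <- list(verts = c(s$verts, v), filt = filt, ext = ext,
                          val = val)
        li <- li + 1
        locs[[li]] <- if (multi) c(filt, val) else filt
        deltas[[li]] <- sign
      }
    }
    level <- nxt[seq_len(ni)]
  }
  contributions(do.call(rbind, locs), unlist(deltas))
}

#' Contributions of the simplices owned by one vertex
#'
#' Emits one contribution \code{(diameter, (-1)^dim)} per simplex whose
#' minimal vertex (in the ordering) is the local graph's center, found by
#' breadth-first extension: start from the singleton (filtration 0,
#' extendables = the neighbors), then repeatedly extend each simplex by
#' one extendable vertex, updating the filtration to the longest new edge
#' and intersecting the extendable set with the new vertex's subsequent
#' neighbors.
#'
#' @param g Local graph from [buildLocalGraph()].
#' @param threshold Diameter bound used when building \code{g}.
#' @return Raw (unaggregated) contribution data.frame.
#' @export
localContributions <- function(g, threshold = Inf) {
  .localContribs(g, threshold)
}

#' Euler characteristic curve of a Vietoris-Rips complex
#'
#' Builds the full contribution list of the Vietoris-Rips flag complex
#' whose simplices are the vertex subsets of diameter (longest pairwise
#' distance) at most \code{threshold}; the filtration value of a simplex
#' is its diameter and vertices enter at 0.  Per-vertex local
#' contributions are independent and are distributed over \code{workers}
#' processes; the aggregated result is invariant to the worker count and
#' to the ordering strategy.
#'
#' @inheritParams orderVertices
#' @param workers Positive integer number of parallel workers.
#' @return An [EulerCurve-class].
#' @examples
#' tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
#' ecValues(eccVR(tri, threshold = 1))   # 3 vertices, then chi = 1
#' @export
eccVR <- function(points, threshold, workers = 1L,
                  strategy = c("given", "ascending_degree"), metric = NULL) {
  buildCurve(vrContributions(points, threshold, workers = workers,
                             strategy = strategy, metric = metric))
}

#' @describeIn eccVR the raw aggregated contribution list
#' @export
vrContributions <- function(points, threshold, workers = 1L,
                            strategy = c("given", "ascending_degree"),
                            metric = NULL) {
  points <- .asPointMatrix(points)
  stopifnot(threshold >= 0, workers >= 1)
  n <- nrow(points)
  if (n == 0) return(contributions(numeric(0), numeric(0)))
  ordering <- orderVertices(points, threshold, strategy, metric)
  task <- function(i) {
    g <- buildLocalGraph(points, ordering, i, threshold, metric)
    localContributions(g, threshold)
  }
  pieces <- if (workers > 1) {
    parallel::mclapply(seq_len(n), task, mc.cores = workers)
  } else {
    lapply(seq_len(n), task)
  }
  aggregateContributions(do.call(rbind, pieces))
}

#' Multiparameter Vietoris-Rips profile
#'
#' Bifiltered (or higher) Vietoris-Rips complex: besides its diameter,
#' every simplex carries \code{m} extra filtration coordinates obtained by
#' extending per-vertex values with a monotone \code{rule} (default:
#' coordinate-wise maximum over the simplex's vertices), giving an
#' (m+1)-parameter profile with locations \code{(diameter, rule values)}.
#' A non-monotone rule is detected on the emitted simplices and rejected.
#'
#' @inheritParams eccVR
#' @param vertexValues Numeric matrix (or vector) of per-vertex filtration
#'   values, one row per point.
#' @param rule Function \code{(parentValue, vertexValue) -> value} applied
#'   when a simplex is extended by one vertex; must be monotone (the
#'   simplex value must dominate every face's value coordinate-wise).
#' @param truncation Optional truncation attached to the returned profile.
#' @return An [EulerProfile-class] of arity \code{ncol(vertexValues) + 1}.
#' @export
vrMultiparameter <- function(points, threshold, vertexValues, workers = 1L,
                             strategy = c("given", "ascending_degree"),
                             rule = NULL, metric = NULL, truncation = NULL) {
  points <- .asPointMatrix(points)
  stopifnot(threshold >= 0)
  if (is.null(dim(vertexValues)))
    vertexValues <- matrix(vertexValues, ncol = 1)
  vertexValues <- as.matrix(vertexValues)
  stopifnot(nrow(vertexValues) == nrow(points))
  n <- nrow(points)
  if (n == 0)
    return(newEulerProfile(
      contributions(matrix(0, 0, ncol(vertexValues) + 1), numeric(0)),
      truncation))
  ordering <- orderVertices(points, threshold, strategy, metric)
  task <- function(i) {
    g <- buildLocalGraph(points, ordering, i, threshold, metric)
    vv <- vertexValues[c(g$center, g$neighbors), , drop = FALSE]
    .localContribs(g, threshold, vertexValues = vv, rule = rule)
  }
  pieces <- if (workers > 1) {
    parallel::mclapply(seq_len(n), task, mc.cores = workers)
  } else {
    lapply(seq_len(n), task)
  }
  newEulerProfile(do.call(rbind, pieces), truncation)
}

#' Codensity vertex filtration
#'
#' For each point, the mean Euclidean distance to its \code{k} nearest
#' neighbors (excluding the point itself), e.g.
#' \eqn{\rho_{10}(p) = \frac{1}{10}\sum_{i=1}^{10} \|p - p_i\|_2}.  High
#' values flag low-density regions, so pairing codensity with the
#' Vietoris-Rips diameter gives a density-aware bifiltration.
#'
#' @param points Numeric matrix, one point per row (more than \code{k}
#'   rows).
#' @param k Number of nearest neighbors.
#' @return Numeric vector of per-point codensities.
#' @export
codensity <- function(points, k) {
  points <- .asPointMatrix(points)
  stopifnot(k >= 1)
  n <- nrow(points)
  if (n <= k) stop(sprintf("codensity with k = %d needs more than %d points", k, k))
  D <- .distMatrix(points)
  vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i], partial = k)[seq_len(k)])
  }, 0)
}
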