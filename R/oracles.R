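# Independent brute-force reference implementations.  Deliberately naive
# (explicit subset enumeration, fully materialized complexes) and sharing
# no code with the engines, so that engine-vs-oracle equality is a
# genuine cross-check.

#' Brute-force Vietoris-Rips complex
#'
#' Enumerates every non-empty vertex subset of a small pointcloud and
#' keeps those whose diameter (longest pairwise Euclidean distance) is at
#' most \code{threshold}; the filtration value of a subset is its
#' diameter.
#'
#' @param points Numeric matrix with at most \code{maxPoints} rows.
#' @param threshold Diameter bound.
#' @param maxPoints Enumeration guard (default 15).
#' @return A "full complex": list with \code{cells} (list of vertex index
#'   sets), \code{dim} (integer vector) and \code{filtration} (one-column
#'   matrix).
#' @export
bruteVR <- function(points, threshold, maxPoints = 15L) {
  points <- .asPointMatrix(points)
  n <- nrow(points)
  if (n > maxPoints)
    stop(sprintf("brute-force enumeration is limited to %d points", maxPoints))
  D <- as.matrix(stats::dist(points))
  cells <- list(); dims <- integer(0); filt <- numeric(0)
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (s in subsets) {
      diam <- if (size == 1) 0 else max(D[s, s])
      if (diam <= threshold) {
        cells[[length(cells) + 1]] <- s
        dims <- c(dims, size - 1L)
        filt <- c(filt, diam)
      }
    }
  }
  list(cells = cells, dim = dims, filtration = matrix(filt, ncol = 1))
}

#' Brute-force cubical complex of an image
#'
#' Materializes every elementary cube of the T-construction: along each
#' axis a cell is either a vertex at integer coordinate \code{0..m} or an
#' interval \code{[l, l+1]} with \code{l in 0..m-1}; its filtration is
#' the (per-channel) minimum of the voxel values over all top cells
#' containing it.
#'
#' @param image Numeric array (channels in the last dimension when
#'   \code{nChannels > 1}).
#' @param nChannels Number of channels.
#' @param maxCells Enumeration guard.
#' @return A full complex as in [bruteVR()]: \code{cells} holds the
#'   per-axis cell codes (even code \code{2l} = vertex at \code{l}, odd
#'   code \code{2l+1} = interval \code{[l, l+1]}), \code{filtration} has
#'   one column per channel.
#' @export
bruteCubical <- function(image, nChannels = 1L, maxCells = 10000L) {
  m <- .imageDims(image, nChannels)
  d <- length(m)
  total <- prod(2 * m + 1)
  if (total > maxCells)
    stop(sprintf("brute-force complex would have %d cells (limit %d)",
                 total, maxCells))
  voxel <- function(idx) vapply(seq_len(nChannels), function(ch) {
    do.call(`[`, c(list(image), as.list(idx), if (nChannels > 1) list(ch)))
  }, 0)
  codes <- do.call(expand.grid, lapply(m, function(mi) 0:(2 * mi)))
  cells <- list(); dims <- integer(0); filt <- list()
  for (r in seq_len(nrow(codes))) {
    code <- as.integer(codes[r, ])
    owners <- vector("list", d)
    dimCell <- 0L
    for (ax in seq_len(d)) {
      if (code[ax] %% 2 == 1) { # interval [l, l+1], 0-based l
        dimCell <- dimCell + 1L
        owners[[ax]] <- (code[ax] - 1L) %/% 2L + 1L # 1-based voxel
      } else {                  # vertex at l
        l <- code[ax] %/% 2L
        owners[[ax]] <- intersect(c(l, l + 1L), seq_len(m[ax]))
      }
    }
    og <- as.matrix(do.call(expand.grid, owners))
    f <- voxel(og[1, ])
    if (nrow(og) > 1) for (r2 in 2:nrow(og)) f <- pmin(f, voxel(og[r2, ]))
    cells[[r]] <- code
    dims <- c(dims, dimCell)
    filt[[r]] <- f
  }
  list(cells = cells, dim = dims, filtration = do.call(rbind, filt))
}

#' Contributions, curve or profile of a fully materialized complex
#'
#' Emits one contribution \code{(filtration, (-1)^dim)} per cell of a
#' full complex (from [bruteVR()] or [bruteCubical()]) and aggregates:
#' a one-parameter filtration yields an [EulerCurve-class], otherwise an
#' [EulerProfile-class].
#'
#' @param complex Full complex list.
#' @param truncation Optional truncation for the profile case.
#' @return [EulerCurve-class] or [EulerProfile-class].
#' @export
complexToCurve <- function(complex, truncation = NULL) {
  contribs <- complexContributions(complex)
  if (ncol(complex$filtration) == 1) buildCurve(contribs)
  else newEulerProfile(contribs, truncation)
}

#' @describeIn complexToCurve the raw (unaggregated) contribution list
#' @export
complexContributions <- function(complex) {
  contributions(complex$filtration, (-1)^complex$dim)
}
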