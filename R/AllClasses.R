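#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Euler characteristic curve
#'
#' An \code{EulerCurve} is a right-continuous integer step function
#' \eqn{t \mapsto \chi(K_t)} over a one-parameter sublevel filtration,
#' stored as its sorted jump points together with the Euler characteristic
#' value attained at (and after) each jump.  Before the first jump the
#' sublevel complex is empty and the curve is 0.
#'
#' @slot jumps Strictly increasing numeric vector of filtration values at
#'   which the Euler characteristic changes.
#' @slot values Numeric vector (integer-valued) of the same length:
#'   \code{values[i]} is the Euler characteristic on
#'   \code{[jumps[i], jumps[i+1])}.
#'
#' @seealso [buildCurve()], [ecAt()], [distanceCurves()], [vectorizeCurve()]
#' @export
setClass("EulerCurve",
  representation(jumps = "numeric", values = "numeric"),
  prototype(jumps = numeric(0), values = numeric(0))
)

setValidity("EulerCurve", function(object) {
  msg <- character(0)
  if (length(object@jumps) != length(object@values))
    msg <- c(msg, "'jumps' and 'values' must have the same length")
  if (anyNA(object@jumps) || anyNA(object@values))
    msg <- c(msg, "'jumps' and 'values' must not contain NA")
  if (length(object@jumps) > 1 && any(diff(object@jumps) <= 0))
    msg <- c(msg, "'jumps' must be strictly increasing")
  if (length(object@values) &&
      max(abs(object@values - round(object@values))) > 0)
    msg <- c(msg, "'values' must be integer-valued")
  if (length(msg)) msg else TRUE
})

#' Euler characteristic profile
#'
#' An \code{EulerProfile} represents an n-parameter Euler characteristic
#' profile \eqn{p \mapsto \chi(K_p)} as a canonical (aggregated,
#' lexicographically sorted) multiset of contributions: integer increments
#' \code{deltas[i]} located at the filtration points \code{locations[i, ]}.
#' The profile value at \code{p} is the sum of all deltas at locations
#' coordinate-wise \code{<= p}.  An optional truncation box \code{[0, f_inf]}
#' per axis can be attached; it is required for finite L1 distances.
#'
#' @slot locations Numeric matrix with one row per contribution and one
#'   column per filtration parameter (n >= 2).
#' @slot deltas Numeric vector (integer-valued) of Euler characteristic
#'   increments, one per row of \code{locations}.
#' @slot truncation Either \code{NULL} or a numeric vector of per-axis
#'   upper bounds \code{f_inf}.
#'
#' @seealso [newEulerProfile()], [ecpAt()], [distanceProfiles()],
#'   [vectorizeProfile()]
#' @export
setClass("EulerProfile",
  representation(locations = "matrix", deltas = "numeric",
                 truncation = "numericOrNULL"),
  prototype(locations = matrix(numeric(0), 0, 2), deltas = numeric(0),
            truncation = NULL)
)

setValidity("EulerProfile", function(object) {
  msg <- character(0)
  if (!is.numeric(object@locations))
    msg <- c(msg, "'locations' must be a numeric matrix")
  if (nrow(object@locations) != length(object@deltas))
    msg <- c(msg, "'deltas' must have one entry per row of 'locations'")
  if (ncol(object@locations) < 2)
    msg <- c(msg, "a profile needs at least 2 filtration parameters; use EulerCurve for 1")
  if (!is.null(object@truncation) &&
      length(object@truncation) != ncol(object@locations))
    msg <- c(msg, "'truncation' length must match the number of parameters")
  if (length(object@deltas) &&
      max(abs(object@deltas - round(object@deltas))) > 0)
    msg <- c(msg, "'deltas' must be integer-valued")
  if (length(msg)) msg else TRUE
})

#' Persistence diagram
#'
#' A finite multiset of (birth, death) pairs of homology classes along a
#' filtration, with \code{birth <= death}.  Diagonal points are implicit
#' (with infinite multiplicity) and never stored.  Used by the empirical
#' stability bench: Betti curves are sums of the indicator functions
#' \eqn{I_{[b,d)}}, and the 1-Wasserstein distance matches points between
#' diagrams, allowing matches to the diagonal.
#'
#' @slot births Numeric vector of birth values.
#' @slot deaths Numeric vector of death values (\code{>= births}).
#' @slot dimension Integer homology dimension label.
#'
#' @seealso [PersistenceDiagram()], [bettiCurve()], [wasserstein1()]
#' @export
setClass("PersistenceDiagram",
  representation(births = "numeric", deaths = "numeric",
                 dimension = "integer"),
  prototype(births = numeric(0), deaths = numeric(0), dimension = 0L)
)

setValidity("PersistenceDiagram", function(object) {
  msg <- character(0)
  if (length(object@births) != length(object@deaths))
    msg <- c(msg, "'births' and 'deaths' must have the same length")
  if (anyNA(object@births) || anyNA(object@deaths))
    msg <- c(msg, "births/deaths must not contain NA")
  if (length(object@births) && any(object@deaths < object@births))
    msg <- c(msg, "every death must be >= its birth")
  if (length(msg)) msg else TRUE
})

#' Construct a persistence diagram
#'
#' @param births,deaths Numeric vectors of equal length with
#'   \code{births <= deaths}.
#' @param dimension Homology dimension label (default 0).
#' @return A [PersistenceDiagram-class] object.
#' @examples
#' PersistenceDiagram(c(0, 1), c(2, 3))
#' @export
PersistenceDiagram <- function(births = numeric(0), deaths = numeric(0),
                               dimension = 0L) {
  new("PersistenceDiagram", births = as.numeric(births),
      deaths = as.numeric(deaths), dimension = as.integer(dimension))
}

#' @describeIn PersistenceDiagram-class birth values
#' @param object,x A \code{PersistenceDiagram}.
#' @export
births <- function(object) object@births

#' @describeIn PersistenceDiagram-class death values
#' @export
deaths <- function(object) object@deaths

setMethod("show", "PersistenceDiagram", function(object) {
  cat(sprintf("PersistenceDiagram (dim %d) with %d point(s)\n",
              object@dimension, length(object@births)))
  if (length(object@births)) {
    k <- min(5L, length(object@births))
    for (i in seq_len(k))
      cat(sprintf("  (%g, %g)\n", object@births[i], object@deaths[i]))
    if (length(object@births) > k) cat("  ...\n")
  }
  invisible(NULL)
})

#' @export
setMethod("length", "PersistenceDiagram", function(x) length(x@births))
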