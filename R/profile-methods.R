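#' @describeIn EulerProfile-class number of filtration parameters
#' @param object,x An \code{EulerProfile}.
#' @export
nParameters <- function(object) ncol(object@locations)

#' @describeIn EulerProfile-class per-axis truncation bound (or NULL)
#' @export
truncation <- function(object) object@truncation

#' @describeIn EulerProfile-class contribution list of the profile
#' @export
profileContributions <- function(object) {
  contributions(object@locations, object@deltas)
}

#' @export
setMethod("length", "EulerProfile", function(x) length(x@deltas))

setMethod("show", "EulerProfile", function(object) {
  cat(sprintf("EulerProfile with %d parameter(s), %d contribution(s)\n",
              ncol(object@locations), length(object@deltas)))
  if (!is.null(object@truncation))
    cat("  truncation: (", paste(signif(object@truncation, 6), collapse = ", "),
        ")\n", sep = "")
  k <- min(5L, length(object@deltas))
  for (i in seq_len(k))
    cat(sprintf("  %+g at (%s)\n", object@deltas[i],
                paste(signif(object@locations[i, ], 6), collapse = ", ")))
  if (length(object@deltas) > k) cat("  ...\n")
  invisible(NULL)
})

#' Evaluate an Euler characteristic profile
#'
#' Returns \eqn{\chi(K_p)}: the sum of the deltas of all contributions at
#' locations coordinate-wise \code{<= p}.  Linear time in the number of
#' contributions.
#'
#' @param profile An [EulerProfile-class].
#' @param p Numeric vector with one entry per filtration parameter.
#' @return Integer-valued scalar.
#' @examples
#' pr <- newEulerProfile(contributions(rbind(c(0, 0)), 1))
#' ecpAt(pr, c(1, 1))
#' @export
ecpAt <- function(profile, p) {
  stopifnot(is(profile, "EulerProfile"))
  if (length(p) != ncol(profile@locations))
    stop(sprintf("query arity %d does not match profile arity %d",
                 length(p), ncol(profile@locations)))
  if (!length(profile@deltas)) return(0)
  below <- profile@locations <= rep(p, each = nrow(profile@locations))
  sum(profile@deltas[rowSums(below) == length(p)])
}
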