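# Contribution lists are plain data.frames: numeric location columns named
# f1..fn followed by an integer-valued 'delta' column.  A raw single-cell
# contribution has delta = (-1)^dim(cell), placed at the cell's (possibly
# vector-valued) filtration value.

#' Create a contribution data.frame
#'
#' @param locations Numeric matrix (one row per contribution) or vector
#'   (one-parameter case).
#' @param deltas Integer-valued vector of Euler characteristic increments.
#' @return A data.frame with columns \code{f1..fn, delta}.
#' @examples
#' contributions(c(0, 1), c(3, -2))
#' @export
contributions <- function(locations, deltas) {
  if (is.null(dim(locations))) locations <- matrix(locations, ncol = 1)
  locations <- as.matrix(locations)
  storage.mode(locations) <- "double"
  stopifnot(nrow(locations) == length(deltas))
  out <- as.data.frame(locations)
  names(out) <- paste0("f", seq_len(ncol(locations)))
  out$delta <- as.numeric(deltas)
  rownames(out) <- NULL
  out
}

.locationCols <- function(contribs) {
  cols <- setdiff(names(contribs), "delta")
  if (!"delta" %in% names(contribs))
    stop("contribution list must have a 'delta' column")
  if (length(cols) < 1)
    stop("contribution list must have at least one filtration column")
  cols
}

.checkContribs <- function(contribs, arity = NULL) {
  cols <- .locationCols(contribs)
  ok <- vapply(contribs[cols], is.numeric, logical(1))
  if (!all(ok))
    stop("malformed input: filtration columns must all be numeric (mixed arities or types)")
  if (!is.null(arity) && length(cols) != arity)
    stop(sprintf("expected %d filtration parameter(s), found %d",
                 arity, length(cols)))
  cols
}

#' Aggregate a raw contribution list
#'
#' Canonicalizes algorithm output: contributions sharing the exact same
#' location are merged by summing their deltas, locations whose deltas
#' cancel to zero are dropped, and the result is sorted lexicographically
#' by location.  The total delta sum is preserved.  Grouping uses exact
#' floating-point equality: duplicate filtration values arise from
#' identical arithmetic, and a tolerance would make the result
#' order-dependent.
#'
#' @param contribs Contribution data.frame (see [contributions()]); all
#'   rows must have the same location arity.
#' @return Aggregated, sorted contribution data.frame.
#' @examples
#' aggregateContributions(contributions(c(0, 0, 1), c(1, 1, -1)))
#' @export
aggregateContributions <- function(contribs) {
  cols <- .checkContribs(contribs)
  if (nrow(contribs) == 0) return(contributions(matrix(0, 0, length(cols)), numeric(0)))
  ord <- do.call(order, unname(contribs[cols]))
  loc <- contribs[ord, cols, drop = FALSE]
  delta <- contribs$delta[ord]
  n <- nrow(loc)
  if (n > 1) {
    same <- rep(TRUE, n - 1)
    for (cl in cols) {
      v <- loc[[cl]]
      same <- same & (v[-1] == v[-n])
    }
    grp <- cumsum(c(TRUE, !same))
  } else grp <- 1L
  delta <- as.numeric(rowsum(delta, grp, reorder = FALSE))
  first <- !duplicated(grp)
  loc <- loc[first, , drop = FALSE]
  keep <- delta != 0
  contributions(as.matrix(loc[keep, , drop = FALSE]), delta[keep])
}

#' Build an Euler characteristic curve from contributions
#'
#' Aggregates a one-parameter contribution list and accumulates the deltas
#' in filtration order into the step function \eqn{t \mapsto \chi(K_t)}.
#'
#' @param contribs Contribution data.frame with a single filtration column.
#' @return An [EulerCurve-class].
#' @examples
#' buildCurve(contributions(c(0, 1), c(3, -2)))
#' @export
buildCurve <- function(contribs) {
  cols <- .checkContribs(contribs)
  if (length(cols) != 1)
    stop("contributions have more than one filtration parameter; use newEulerProfile()")
  agg <- aggregateContributions(contribs)
  new("EulerCurve", jumps = agg$f1, values = cumsum(agg$delta))
}

#' Build an Euler characteristic profile from contributions
#'
#' @param contribs Contribution data.frame with n >= 2 filtration columns.
#' @param truncation Optional per-axis upper bound \code{f_inf} attached to
#'   the profile (used as the default integration box for distances).
#' @return An [EulerProfile-class] with aggregated, sorted contributions.
#' @examples
#' newEulerProfile(contributions(rbind(c(0, 0)), 1), truncation = c(1, 1))
#' @export
newEulerProfile <- function(contribs, truncation = NULL) {
  cols <- .checkContribs(contribs)
  if (length(cols) < 2)
    stop("a profile needs at least 2 filtration parameters; use buildCurve()")
  agg <- aggregateContributions(contribs)
  loc <- as.matrix(agg[cols])
  storage.mode(loc) <- "double"
  new("EulerProfile", locations = loc,
      deltas = agg$delta,
      truncation = if (is.null(truncation)) NULL else as.numeric(truncation))
}

#' Read / write contribution lists as CSV
#'
#' Contribution lists serialize as CSV with one row per contribution,
#' location columns \code{f1..fn} and a \code{delta} column; a header row
#' names the filtration axes.  Floats are written with full precision so
#' that round trips are bit-exact.
#'
#' @param path File path.
#' @param contribs Contribution data.frame.
#' @return \code{readContributions} returns a contribution data.frame;
#'   \code{writeContributions} returns \code{path} invisibly.
#' @export
readContributions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df[] <- lapply(df, as.numeric)  # zero-row files parse as logical
  .checkContribs(df)
  df
}

#' @rdname readContributions
#' @export
writeContributions <- function(contribs, path) {
  .checkContribs(contribs)
  out <- contribs
  for (cl in names(out))
    out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
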