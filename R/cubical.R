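# Streaming ECC/ECP contributions for cubical complexes built from
# n-dimensional single- or multi-channel images (T-construction: voxels
# are the top-dimensional cells, faces get the coordinate-wise minimum of
# the voxel values over the top cells containing them).
#
# Cell ownership partitions the full closed complex: along every axis a
# cell is, for its owner voxel x, either the voxel's own nondegenerate
# interval [x, x+1], the shared face at x+1 (shared with the voxel at
# +1 offset; at the image's high edge it is unshared and still owned by
# x), or -- only when x is the first voxel on that axis -- the unshared
# boundary face at x.  This gives 2^d cells per generic interior voxel
# (Fig.-9-style pairing with the +1 offsets) and prod(2*m_i + 1) cells in
# total, every cell exactly once.

.imageDims <- function(image, nChannels) {
  d <- dim(image)
  if (is.null(d)) d <- length(image)
  if (nChannels > 1) {
    if (length(d) < 2 || d[length(d)] != nChannels)
      stop("ragged channels: last array dimension must hold the channels")
    d <- d[-length(d)]
  }
  as.integer(d)
}

# per-axis coordinate id (0-based) of each linear position of an array
.axisId <- function(dims, axis) {
  stride <- prod(dims[seq_len(axis - 1)])
  ((seq_len(prod(dims)) - 1) %/% stride) %% dims[axis]
}

# min(x[l], x[l+1]) along an axis (last position keeps its own value):
# filtration of the shared face at coordinate l+1
.axisPairMin <- function(x, dims, axis) {
  m <- dims[axis]
  if (m == 1) return(x)
  id <- .axisId(dims, axis)
  stride <- prod(dims[seq_len(axis - 1)])
  shifted <- ifelse(id < m - 1, seq_along(x) + stride, seq_along(x))
  pmin(x, x[shifted])
}

# restrict to the first slice along an axis (low-boundary faces)
.axisFirst <- function(x, dims, axis) {
  keep <- .axisId(dims, axis) == 0
  list(x = x[keep], dims = replace(dims, axis, 1L))
}

# Contributions owned by the voxels of one slab (one coordinate of the
# streaming axis), given the slab values and, when present, the next
# slab.  `vals` / `nextVals` are lists with one numeric vector per
# channel, laid out with dims `sdims` (the non-streamed axes).
.slabContribs <- function(vals, nextVals, sdims, firstSlab) {
  d <- length(sdims) + 1L
  lastKinds <- c("A", "B", if (firstSlab) "C")
  # kind codes per non-streamed axis: A = nondegenerate interval,
  # B = shared/high face at +1, C = low-boundary face (first voxel only)
  kindSets <- rep(list(c("A", "B", "C")), length(sdims))
  combos <- if (length(sdims)) do.call(expand.grid,
                                       c(kindSets, stringsAsFactors = FALSE))
            else data.frame(row.names = 1)
  out <- vector("list", nrow(combos) * length(lastKinds))
  oi <- 0
  for (lk in lastKinds) {
    base <- switch(lk,
      A = vals,
      B = if (is.null(nextVals)) vals else Map(pmin, vals, nextVals),
      C = vals)
    baseDim <- as.integer(1) # dims along streaming axis collapse to 1 cell
    for (ci in seq_len(nrow(combos))) {
      x <- base
      dims <- sdims
      dimCells <- if (lk == "A") 1L else 0L
      ok <- TRUE
      if (length(sdims)) for (ax in seq_along(sdims)) {
        kind <- combos[ci, ax]
        if (kind == "A") {
          dimCells <- dimCells + 1L
        } else if (kind == "B") {
          x <- lapply(x, .axisPairMin, dims = dims, axis = ax)
        } else { # C: unshared low-boundary face
          res <- lapply(x, .axisFirst, dims = dims, axis = ax)
          x <- lapply(res, `[[`, "x")
          dims <- res[[1]]$dims
        }
      }
      if (!ok) next
      loc <- do.call(cbind, x)
      oi <- oi + 1
      out[[oi]] <- contributions(loc, rep((-1)^dimCells, nrow(loc)))
    }
  }
  do.call(rbind, out[seq_len(oi)])
}

# Full contribution list of the T-construction complex, streamed along
# the last spatial axis: only a 2-slab window of the image is accessed at
# each step.
.cubicalContribs <- function(image, nChannels) {
  sdimsAll <- .imageDims(image, nChannels)
  d <- length(sdimsAll)
  if (prod(sdimsAll) == 0)
    return(contributions(matrix(0, 0, max(nChannels, 1)), numeric(0)))
  image <- as.numeric(image) # column-major: spatial axes first, channels last
  nSpatial <- prod(sdimsAll)
  sliceAxis <- d
  m <- sdimsAll[sliceAxis]
  sdims <- sdimsAll[-sliceAxis]
  sliceLen <- prod(sdims)
  getSlab <- function(z) { # z is 1-based slab index; list per channel
    lapply(seq_len(nChannels), function(ch) {
      offset <- (ch - 1) * nSpatial + (z - 1) * sliceLen
      image[offset + seq_len(sliceLen)]
    })
  }
  pieces <- vector("list", m)
  slab <- getSlab(1)
  for (z in seq_len(m)) {
    nxt <- if (z < m) getSlab(z + 1) else NULL
    pieces[[z]] <- .slabContribs(slab, nxt, sdims, firstSlab = z == 1)
    if (!is.null(nxt)) slab <- nxt
  }
  do.call(rbind, pieces)
}

#' Contributions of one voxel's upper closure
#'
#' The upper closure of a voxel is its top-dimensional cell plus the
#' faces it owns: along every axis either the full interval, the face
#' shared with the voxel at +1 offset (owned by this voxel, also when it
#' lies on the image's high edge), or -- for the first voxel on an axis --
#' the unshared low-boundary face.  Each cell contributes
#' \code{(-1)^dim} at the coordinate-wise minimum of the voxel values
#' over the top cells containing it (per channel for multi-channel
#' images).  Upper closures partition the full complex, so summing them
#' over all voxels enumerates every cell exactly once.
#'
#' @param image Numeric array (spatial axes first; for
#'   \code{nChannels > 1} the last dimension holds the channels).
#' @param voxel Integer vector of 1-based voxel indices, one per spatial
#'   axis.
#' @param nChannels Number of value channels per voxel.
#' @return Raw contribution data.frame (arity \code{nChannels}).
#' @export
upperClosureContributions <- function(image, voxel, nChannels = 1L) {
  sdims <- .imageDims(image, nChannels)
  if (length(voxel) != length(sdims) || any(voxel < 1) || any(voxel > sdims))
    stop("voxel index out of range")
  vox <- as.integer(voxel)
  getVal <- function(idx) { # per-channel value of one voxel
    vapply(seq_len(nChannels), function(ch) {
      ijk <- c(as.list(idx), if (nChannels > 1) list(ch))
      do.call(`[`, c(list(image), ijk))
    }, 0)
  }
  d <- length(sdims)
  perAxis <- lapply(seq_len(d), function(ax) {
    kinds <- list(list(kind = "A"), list(kind = "B"))
    if (vox[ax] == 1) kinds <- c(kinds, list(list(kind = "C")))
    kinds
  })
  combos <- do.call(expand.grid, c(lapply(perAxis, seq_along)))
  locs <- list(); deltas <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    owners <- vector("list", d); dimCells <- 0L
    for (ax in seq_len(d)) {
      kind <- perAxis[[ax]][[combos[ci, ax]]]$kind
      owners[[ax]] <- switch(kind,
        A = { dimCells <- dimCells + 1L; vox[ax] },
        B = intersect(c(vox[ax], vox[ax] + 1L), seq_len(sdims[ax])),
        C = vox[ax])
    }
    og <- as.matrix(do.call(expand.grid, owners))
    filt <- Reduce(pmin, lapply(seq_len(nrow(og)), function(r) getVal(og[r, ])))
    locs[[ci]] <- filt
    deltas[ci] <- (-1)^dimCells
  }
  contributions(do.call(rbind, locs), deltas)
}

#' Euler characteristic curve of a grayscale image
#'
#' Streams over the image in a sliding two-slab window along the last
#' axis, accumulating the upper-closure contributions of every voxel of
#' the T-construction cubical complex, then aggregates them into the
#' curve.  Equals the curve of the fully materialized complex.
#'
#' @param image Numeric array of scalar voxel values (any dimension).
#' @return An [EulerCurve-class].
#' @examples
#' ecValues(eccCubical(matrix(5, 3, 3)))   # contractible block: chi = 1
#' @export
eccCubical <- function(image) {
  buildCurve(.cubicalContribs(image, nChannels = 1L))
}

#' Euler characteristic profile of a multi-channel image
#'
#' Same streaming traversal as [eccCubical()], with the filtration of each
#' cell being the coordinate-wise (per-channel) minimum over the top cells
#' containing it, giving one filtration parameter per channel.
#'
#' @param image Numeric array whose last dimension indexes the
#'   \code{nChannels >= 2} channels.
#' @param nChannels Number of channels (default: size of the last array
#'   dimension).
#' @param truncation Optional truncation attached to the profile (for
#'   8-bit images a natural choice is 256 per axis).
#' @return An [EulerProfile-class] of arity \code{nChannels}.
#' @export
ecpCubical <- function(image, nChannels = dim(image)[length(dim(image))],
                       truncation = NULL) {
  if (is.null(nChannels) || nChannels < 2)
    stop("ecpCubical needs at least 2 channels; use eccCubical for scalar images")
  newEulerProfile(.cubicalContribs(image, nChannels = as.integer(nChannels)),
                  truncation = truncation)
}

#' Read an image file as a numeric array
#'
#' PNG and TIFF rasters are read with the \pkg{png} / \pkg{tiff} packages
#' and rescaled to the 0--255 range (alpha channels are dropped).
#'
#' @param path Path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return Numeric array: \code{height x width} for grayscale input,
#'   \code{height x width x channels} otherwise.
#' @export
readImageArray <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 4)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3 && dim(img)[3] == 1)
    img <- img[, , 1]
  round(img * 255)
}
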