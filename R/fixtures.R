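# Synthetic data generators: noisy spheres, RGB texture images and random
# persistence diagrams.  All generators are pure functions of their seed
# (the global RNG state is saved and restored).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Sample a noisy sphere
#'
#' Draws \code{n} points uniformly on the unit \code{dim}-sphere
#' (embedded in \code{R^(dim+1)}, via normalized Gaussian vectors) and
#' adds isotropic Gaussian coordinate noise of standard deviation
#' \code{noise}.
#'
#' @param n Number of points.
#' @param dim Sphere dimension (a circle is \code{dim = 1}).
#' @param noise Noise standard deviation (0 for exact samples).
#' @param seed Integer seed; identical seeds give identical clouds.
#' @return Numeric matrix \code{n x (dim + 1)}.
#' @export
sampleSphere <- function(n, dim, noise = 0, seed = 0L) {
  stopifnot(n >= 1, dim >= 1, noise >= 0)
  .withSeed(seed, {
    g <- matrix(stats::rnorm(n * (dim + 1)), n, dim + 1)
    x <- g / sqrt(rowSums(g^2))
    if (noise > 0) x <- x + matrix(stats::rnorm(length(x), sd = noise),
                                   n, dim + 1)
    x
  })
}

#' Synthetic RGB texture image
#'
#' Generates a \code{size x size x 3} 8-bit RGB image whose named channel
#' carries a pure binary pattern -- \code{"stripes"} (bands of width
#' \code{period} along the rows) or \code{"checks"} (a parity
#' checkerboard of \code{period}-sized tiles) -- at levels 0/255, while
#' the other channels are 0.  I.i.d. Gaussian pixel noise of standard
#' deviation \code{noiseSigma} is then added to every pixel of every
#' channel and the result is clamped to \code{[0, 255]} and rounded, so
#' the output is a valid 8-bit image.
#'
#' @param style \code{"stripes"} or \code{"checks"}.
#' @param color \code{"red"}, \code{"green"} or \code{"blue"}: the
#'   channel carrying the pattern.
#' @param size Pixels per side (>= 4).
#' @param period Pattern period in pixels (default \code{size / 8}).
#' @param noiseSigma Noise standard deviation on the 0--255 scale.
#' @param seed Integer seed.
#' @return Numeric array \code{size x size x 3} of integers in 0--255.
#' @export
textureImage <- function(style = c("stripes", "checks"),
                         color = c("red", "green", "blue"),
                         size = 64L, period = max(1L, size %/% 8L),
                         noiseSigma = 10, seed = 0L) {
  style <- match.arg(style)
  color <- match.arg(color)
  stopifnot(size >= 4)
  band <- function(i) (i - 1) %/% period
  pattern <- if (style == "stripes") {
    outer(band(seq_len(size)), rep(0L, size), `+`) %% 2
  } else {
    outer(band(seq_len(size)), band(seq_len(size)), `+`) %% 2
  }
  img <- array(0, dim = c(size, size, 3))
  img[, , match(color, c("red", "green", "blue"))] <- pattern * 255
  .withSeed(seed, {
    img <- img + array(stats::rnorm(length(img), sd = noiseSigma), dim(img))
  })
  round(pmin(pmax(img, 0), 255))
}

#' Batch of synthetic textures
#'
#' The full texture study set: \code{nPerClass} samples of each of the
#' 6 style/color combinations (2 styles x 3 colors), with deterministic
#' per-image seeds derived from \code{seed}.
#'
#' @inheritParams textureImage
#' @param nPerClass Samples per style/color combination (default 10).
#' @return List with \code{images} (list of arrays), \code{style} and
#'   \code{color} (character vectors of labels).
#' @export
textureBatch <- function(nPerClass = 10L, size = 64L,
                         period = max(1L, size %/% 8L), noiseSigma = 10,
                         seed = 0L) {
  styles <- c("stripes", "checks")
  colors <- c("red", "green", "blue")
  images <- list(); styleLab <- character(0); colorLab <- character(0)
  k <- 0L
  for (st in styles) for (co in colors) for (i in seq_len(nPerClass)) {
    k <- k + 1L
    images[[k]] <- textureImage(st, co, size = size, period = period,
                                noiseSigma = noiseSigma, seed = seed + k)
    styleLab[k] <- st
    colorLab[k] <- co
  }
  list(images = images, style = styleLab, color = colorLab)
}

#' Random persistence diagram
#'
#' Births are uniform in \code{birthRange}; deaths are the births plus a
#' uniform positive persistence drawn from \code{persistenceRange}, so
#' every point satisfies \code{birth <= death} and all points are finite.
#'
#' @param nPoints Number of off-diagonal points (may be 0).
#' @param birthRange,persistenceRange Length-2 numeric ranges.
#' @param seed Integer seed.
#' @param dimension Homology dimension label.
#' @return A [PersistenceDiagram-class].
#' @export
randomDiagram <- function(nPoints, birthRange = c(0, 5),
                          persistenceRange = c(0, 5), seed = 0L,
                          dimension = 0L) {
  stopifnot(nPoints >= 0)
  .withSeed(seed, {
    b <- stats::runif(nPoints, birthRange[1], birthRange[2])
    p <- stats::runif(nPoints, persistenceRange[1], persistenceRange[2])
    PersistenceDiagram(b, b + p, dimension)
  })
}

#' Random Euler characteristic profile
#'
#' Test/bench plumbing: \code{nCells} unit-magnitude contributions
#' (random \code{(-1)^dim} signs) at uniform locations in
#' \code{[0, fInf]^arity}.
#'
#' @param nCells Number of cell contributions.
#' @param arity Number of filtration parameters (>= 2).
#' @param fInf Upper bound of the location range.
#' @param seed Integer seed.
#' @return An [EulerProfile-class] with \code{truncation = rep(fInf, arity)}.
#' @export
randomProfile <- function(nCells, arity = 2L, fInf = 1, seed = 0L) {
  stopifnot(nCells >= 1, arity >= 2)
  .withSeed(seed, {
    loc <- matrix(stats::runif(nCells * arity, 0, fInf), nCells, arity)
    dlt <- (-1)^sample(0:1, nCells, replace = TRUE)
    newEulerProfile(contributions(loc, dlt), truncation = rep(fInf, arity))
  })
}
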