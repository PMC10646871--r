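# Naive reference implementations used only inside the tests; they share
# no code with the package internals.

# dictionary-style aggregation: exact float keys via full-precision strings
naiveAggregate <- function(contribs) {
  cols <- setdiff(names(contribs), "delta")
  keys <- apply(contribs[cols], 1, function(r)
    paste(sprintf("%.17g", r), collapse = "|"))
  sums <- tapply(contribs$delta, keys, sum)
  sums <- sums[sums != 0]
  loc <- do.call(rbind, lapply(strsplit(names(sums), "|", fixed = TRUE),
                               as.numeric))
  if (is.null(loc)) loc <- matrix(0, 0, length(cols))
  out <- contributions(loc, as.numeric(sums))
  out[do.call(order, unname(out[seq_along(cols)])), , drop = FALSE]
}

# linear-scan curve evaluation
naiveEcAt <- function(curve, t) {
  js <- jumps(curve); vs <- ecValues(curve)
  vapply(t, function(tt) {
    best <- 0
    for (i in seq_along(js)) if (js[i] <= tt) best <- vs[i]
    best
  }, 0)
}

# profile evaluation straight from a contribution data.frame
naiveEcpAt <- function(contribs, p) {
  cols <- setdiff(names(contribs), "delta")
  tot <- 0
  for (r in seq_len(nrow(contribs))) {
    if (all(as.numeric(contribs[r, cols]) <= p)) tot <- tot + contribs$delta[r]
  }
  tot
}

# exhaustive 1-Wasserstein by recursive enumeration of every injection of
# A-points into B-points, the rest projected to the diagonal
naiveW1 <- function(a, b) {
  ab <- cbind(births(a), deaths(a))
  bb <- cbind(births(b), deaths(b))
  diagCost <- function(p) (p[2] - p[1]) / 2
  rec <- function(i, usedB) {
    if (i > nrow(ab)) {
      rest <- setdiff(seq_len(nrow(bb)), usedB)
      return(sum(vapply(rest, function(j) diagCost(bb[j, ]), 0)))
    }
    best <- diagCost(ab[i, ]) + rec(i + 1, usedB)
    for (j in setdiff(seq_len(nrow(bb)), usedB)) {
      c1 <- max(abs(ab[i, ] - bb[j, ])) + rec(i + 1, c(usedB, j))
      if (c1 < best) best <- c1
    }
    best
  }
  rec(1, integer(0))
}

# dense Riemann-sum L1 distance between two curves on [lo, hi]
riemannDistance <- function(a, b, lo, hi, step = 1e-4) {
  ts <- seq(lo, hi, by = step)
  sum(abs(ecAt(a, ts) - ecAt(b, ts))) * step
}

randomCloud <- function(n, d, seed) {
  set.seed(seed)
  matrix(runif(n * d), n, d)
}

# random pairwise-incomparable integer entry points: a staircase in the
# first two coordinates (strictly increasing x, strictly decreasing y)
# makes every pair incomparable whatever the remaining coordinates are
randomAntichain <- function(k, n, seed) {
  set.seed(seed)
  x <- sort(sample(0:9, k))
  y <- sort(sample(0:9, k), decreasing = TRUE)
  extra <- if (n > 2)
    matrix(sample(0:9, k * (n - 2), replace = TRUE), k, n - 2)
  pts <- cbind(x, y, extra)
  dimnames(pts) <- NULL
  pts
}

expect_same_contribs <- function(a, b) {
  a <- aggregateContributions(a)
  b <- aggregateContributions(b)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}

# raw (unaggregated) V-R contribution count = number of simplices emitted
countVRSimplices <- function(points, threshold,
                             strategy = "given") {
  ordering <- orderVertices(points, threshold, strategy)
  total <- 0L
  for (i in seq_along(ordering)) {
    g <- buildLocalGraph(points, ordering, i, threshold)
    total <- total + nrow(localContributions(g, threshold))
  }
  total
}
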