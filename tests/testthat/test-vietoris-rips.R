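unitTriangle <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))

test_that("ascending-degree ordering puts hubs last and breaks ties by index", {
  # star: hub at origin, 4 leaves within threshold of the hub only
  star <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  ord <- orderVertices(star, threshold = 1.2, strategy = "ascending_degree")
  expect_equal(ord[5], 1)  # the hub comes last

  far <- diag(100, 4)
  expect_equal(orderVertices(far, 1, "ascending_degree"), 1:4)
  expect_equal(orderVertices(far, 1, "given"), 1:4)
})

test_that("hub-last ordering balances the local simplex trees", {
  # two hubs, each adjacent to 3 private leaves and to each other
  leaves <- rbind(c(0, 1), c(-0.7, -0.7), c(0.7, -0.7))
  hubs <- rbind(c(0, 0), c(10, 0))
  pts <- rbind(hubs[1, ], leaves, hubs[2, ], sweep(leaves, 2, c(10, 0), "+"))
  treeSizes <- function(strategy) {
    ordering <- orderVertices(pts, 1.2, strategy)
    vapply(seq_along(ordering), function(i)
      nrow(localContributions(buildLocalGraph(pts, ordering, i, 1.2), 1.2)),
      0)
  }
  given <- treeSizes("given")        # hubs first: they own everything
  balanced <- treeSizes("ascending_degree")
  expect_lt(max(balanced), max(given))
  expect_equal(sum(balanced), sum(given))  # same simplex multiset overall
})

test_that("local graphs hold exactly the subsequent in-threshold neighbors", {
  g <- buildLocalGraph(unitTriangle, 1:3, 1, threshold = 1)
  expect_equal(sort(g$neighbors), c(2, 3))
  expect_equal(dim(g$dist), c(3, 3))
  expect_true(all(abs(g$dist - t(g$dist)) < 1e-12))
  expect_equal(diag(g$dist), rep(0, 3))

  gLast <- buildLocalGraph(unitTriangle, 1:3, 3, threshold = 1)
  expect_equal(gLast$neighbors, integer(0))

  # union over vertices of local edges recovers the neighborhood graph
  pts <- randomCloud(15, 2, seed = 5)
  thr <- 0.4
  edges <- list()
  for (i in 1:15) {
    g <- buildLocalGraph(pts, 1:15, i, thr)
    for (j in g$neighbors) edges[[length(edges) + 1]] <- c(i, j)
  }
  got <- do.call(rbind, edges)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  D <- as.matrix(dist(pts))
  want <- which(upper.tri(D) & D <= thr, arr.ind = TRUE)
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  dimnames(want) <- NULL
  expect_equal(got, want)
})

test_that("local contributions enumerate the simplices owned by the center", {
  # isolated vertex
  lone <- buildLocalGraph(rbind(c(0, 0), c(5, 5)), 1:2, 1, threshold = 1)
  lc <- localContributions(lone, 1)
  expect_equal(lc, contributions(0, 1))

  # triangle seen from vertex 1: vertex, 2 edges, 1 triangle
  g <- buildLocalGraph(unitTriangle, 1:3, 1, threshold = 1)
  lc <- aggregateContributions(localContributions(g, 1))
  expect_equal(lc$f1, c(0, 1))
  expect_equal(lc$delta, c(1, -1))  # +1 vertex; -1-1+1 at diameter 1

  # against brute-force enumeration of subsets containing the center
  pts <- randomCloud(9, 3, seed = 21)
  thr <- 0.8
  full <- bruteVR(pts, thr)
  own <- vapply(full$cells, function(s) min(s) == 1, NA)
  oracle <- contributions(full$filtration[own, 1], (-1)^full$dim[own])
  g <- buildLocalGraph(pts, 1:9, 1, thr)
  expect_same_contribs(localContributions(g, thr), oracle)
})

test_that("the V-R curve matches brute-force subset enumeration", {
  cv <- eccVR(unitTriangle, threshold = 1)
  expect_equal(jumps(cv), c(0, 1))
  expect_equal(ecValues(cv), c(3, 1))

  # n isolated points: constant curve at n
  far <- cbind(seq(0, 50, by = 10), 0)
  cv2 <- eccVR(far, threshold = 1)
  expect_equal(ecValues(cv2), 6)

  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1)
    pts <- randomCloud(n, sample(2:4, 1), seed = seed + 100)
    thr <- runif(1, 0.2, 1)
    engine <- eccVR(pts, thr)
    oracle <- complexToCurve(bruteVR(pts, thr))
    expect_equal(jumps(engine), jumps(oracle))
    expect_equal(ecValues(engine), ecValues(oracle))
  }
})

test_that("the curve is invariant to workers and ordering strategy", {
  pts <- randomCloud(25, 2, seed = 9)
  thr <- 0.35
  base <- vrContributions(pts, thr, workers = 1, strategy = "given")
  expect_equal(vrContributions(pts, thr, workers = 2), base)
  expect_equal(vrContributions(pts, thr, workers = 4), base)
  expect_equal(vrContributions(pts, thr, strategy = "ascending_degree"), base)
})

test_that("terminal EC is 1 once the threshold reaches the diameter", {
  pts <- randomCloud(9, 3, seed = 2)
  thr <- max(dist(pts)) * 1.01
  cv <- eccVR(pts, thr)
  expect_equal(ecValues(cv)[length(cv)], 1)
})

test_that("n mutually close points produce 2^n - 1 simplices", {
  for (n in c(4, 8, 10)) {
    pts <- randomCloud(n, 2, seed = n) * 0.01
    expect_equal(countVRSimplices(pts, 1), 2^n - 1)
  }
})

test_that("multiparameter V-R extends vertex values with the max rule", {
  # single vertex with value v
  pr <- vrMultiparameter(rbind(c(0, 0)), 1, vertexValues = 3)
  expect_equal(profileContributions(pr), contributions(rbind(c(0, 3)), 1))

  # edge between vertices valued a < b, length L
  pts <- rbind(c(0, 0), c(0.5, 0))
  pr <- vrMultiparameter(pts, 1, vertexValues = c(1, 2))
  expect_equal(profileContributions(pr),
               contributions(rbind(c(0, 1), c(0, 2), c(0.5, 2)), c(1, 1, -1)))

  # codensity bifiltration of circle samples vs brute-force enumeration
  pts <- sampleSphere(14, 1, noise = 0.05, seed = 4)
  rho <- codensity(pts, k = 5)
  thr <- 0.9
  pr <- vrMultiparameter(pts, thr, vertexValues = rho,
                         strategy = "ascending_degree", workers = 2)
  full <- bruteVR(pts, thr)
  oLoc <- t(vapply(seq_along(full$cells), function(i)
    c(full$filtration[i, 1], max(rho[full$cells[[i]]])), numeric(2)))
  oracle <- newEulerProfile(contributions(oLoc, (-1)^full$dim))
  expect_equal(pr@locations, oracle@locations)
  expect_equal(pr@deltas, oracle@deltas)
})

test_that("non-monotone extension rules are rejected", {
  pts <- rbind(c(0, 0), c(0.5, 0))
  expect_error(
    vrMultiparameter(pts, 1, vertexValues = c(1, 2),
                     rule = function(parent, vertex) pmin(parent, vertex)),
    "monotone")
})

test_that("codensity is the mean distance to the k nearest neighbors", {
  # regular 11-gon: symmetry forces equal values
  th <- 2 * pi * (0:10) / 11
  ring <- cbind(cos(th), sin(th))
  rho <- codensity(ring, k = 10)
  expect_equal(max(rho) - min(rho), 0, tolerance = 1e-12)

  # coincident neighbors give 0
  pile <- matrix(0, 11, 2)
  expect_equal(codensity(pile, 10), rep(0, 11))

  # against a full distance-matrix sort
  pts <- randomCloud(30, 3, seed = 13)
  D <- as.matrix(dist(pts))
  want <- vapply(1:30, function(i) mean(sort(D[i, -i])[1:7]), 0)
  expect_equal(codensity(pts, 7), want)

  expect_error(codensity(randomCloud(5, 2, 1), k = 10), "more than")
})
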