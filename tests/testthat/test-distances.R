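randomCurve <- function(nJumps, seed, balanced = TRUE) {
  set.seed(seed)
  f <- sort(runif(nJumps))
  d <- sample(c(-1, 1), nJumps, replace = TRUE)
  if (balanced) d[nJumps] <- d[nJumps] - sum(d)  # curves that end at 0
  buildCurve(contributions(f, d))
}

test_that("curve distance: identity, rectangle, and unbounded detection", {
  a <- buildCurve(contributions(c(0, 0.5), c(2, -1)))
  expect_equal(distanceCurves(a, a), 0)

  one <- buildCurve(contributions(0, 1))
  zero <- buildCurve(contributions(numeric(0), numeric(0)))
  expect_equal(distanceCurves(one, zero, upper = 2), 2)

  # tails differ and no upper bound: the integral diverges
  expect_error(distanceCurves(one, zero), "unbounded")
})

test_that("curve distance agrees with dense Riemann sums", {
  for (seed in 1:8) {
    a <- randomCurve(12, seed)
    b <- randomCurve(9, seed + 50)
    got <- distanceCurves(a, b)
    ref <- riemannDistance(a, b, lo = -0.1, hi = 1.1)
    expect_equal(got, ref, tolerance = 1e-3)
    # truncated version
    gotU <- distanceCurves(a, b, upper = 0.6)
    refU <- riemannDistance(a, b, lo = -0.1, hi = 0.6 - 1e-9)
    expect_equal(gotU, refU, tolerance = 1e-3)
  }
})

test_that("profile distance: identity, unit cone, Fig-5-style closed form", {
  a <- newEulerProfile(contributions(rbind(c(0, 0), c(0.5, 0.25)), c(1, -1)))
  expect_equal(distanceProfiles(a, a, truncation = c(1, 1)), 0)

  cone <- newEulerProfile(contributions(rbind(c(0, 0)), 1))
  none <- newEulerProfile(contributions(matrix(0, 0, 2), numeric(0)))
  expect_equal(distanceProfiles(cone, none, truncation = c(1, 1)), 1)
  expect_error(distanceProfiles(cone, none), "truncation")

  # a vertex at g vs the same vertex shifted by eps along one axis:
  # difference is the rectangle [g1, g1+eps] x [g2, fInf]
  g <- c(0.2, 0.35); eps <- 0.04
  for (fInf in c(1, 2, 7)) {
    p1 <- newEulerProfile(contributions(rbind(g), 1))
    p2 <- newEulerProfile(contributions(rbind(c(g[1] + eps, g[2])), 1))
    d <- distanceProfiles(p1, p2, truncation = c(fInf, fInf))
    expect_equal(d, eps * (fInf - g[2]))   # grows linearly with fInf
    # and respects the perturbation bound |K| * n * eps^(n-1) * fInf
    expect_lte(d, 1 * 2 * eps * fInf)
  }
})

test_that("profile distance matches brute-force integration on random profiles", {
  for (seed in 1:6) {
    a <- randomProfile(12, arity = 2, fInf = 1, seed = seed)
    b <- randomProfile(10, arity = 2, fInf = 1, seed = seed + 99)
    got <- distanceProfiles(a, b, truncation = c(1, 1))
    # midpoint Riemann sum on a fine regular grid
    step <- 1 / 200
    ts <- seq(step / 2, 1 - step / 2, by = step)
    ref <- 0
    for (x in ts) ref <- ref + sum(vapply(ts, function(y)
      abs(ecpAt(a, c(x, y)) - ecpAt(b, c(x, y))), 0)) * step^2
    expect_equal(got, ref, tolerance = 2e-2)
  }
})

test_that("profile distance is a metric on a fixed truncation box", {
  ps <- lapply(1:3, function(s) randomProfile(8, 2, 1, seed = s))
  tr <- c(1, 1)
  for (i in 1:3) for (j in 1:3) {
    dij <- distanceProfiles(ps[[i]], ps[[j]], truncation = tr)
    dji <- distanceProfiles(ps[[j]], ps[[i]], truncation = tr)
    expect_equal(dij, dji)                      # symmetry
    if (i == j) expect_equal(dij, 0)
    for (k in 1:3) {
      dik <- distanceProfiles(ps[[i]], ps[[k]], truncation = tr)
      dkj <- distanceProfiles(ps[[k]], ps[[j]], truncation = tr)
      expect_lte(dij, dik + dkj + 1e-12)        # triangle inequality
    }
  }
})

test_that("the profile machinery reproduces curve distances on a dummy axis", {
  # embed 1-parameter curves as 2-parameter profiles with a constant
  # second coordinate: the distances must agree on matching truncations
  for (seed in 1:4) {
    ca <- curveContributions(randomCurve(10, seed))
    cb <- curveContributions(randomCurve(7, seed + 10))
    a2 <- newEulerProfile(contributions(cbind(ca$f1, 0), ca$delta))
    b2 <- newEulerProfile(contributions(cbind(cb$f1, 0), cb$delta))
    upper <- 1.5
    expect_equal(
      distanceProfiles(a2, b2, truncation = c(upper, 1)),
      distanceCurves(randomCurve(10, seed), randomCurve(7, seed + 10),
                     upper = upper))
  }
})

test_that("curve L1 distance obeys the diagram stability bound", {
  # ECC = beta_0 - beta_1; its distance is bounded by the summed
  # 2 * W1 distances of the per-dimension diagrams
  for (seed in 1:10) {
    d0a <- randomDiagram(4, seed = seed)
    d0b <- randomDiagram(3, seed = seed + 1000)
    d1a <- randomDiagram(3, seed = seed + 2000)
    d1b <- randomDiagram(4, seed = seed + 3000)
    ecc <- function(d0, d1) {
      c0 <- curveContributions(bettiCurve(d0))
      c1 <- curveContributions(bettiCurve(d1))
      buildCurve(contributions(c(c0$f1, c1$f1), c(c0$delta, -c1$delta)))
    }
    lhs <- distanceCurves(ecc(d0a, d1a), ecc(d0b, d1b))
    rhs <- 2 * wasserstein1(d0a, d0b) + 2 * wasserstein1(d1a, d1b)
    expect_lte(lhs, rhs + 1e-9)
  }
})
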