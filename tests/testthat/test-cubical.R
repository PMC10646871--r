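# helper: full in-memory contribution list by looping the per-voxel
# upper closures explicitly (no streaming)
allClosures <- function(image, nChannels = 1L) {
  d <- dim(image)
  if (is.null(d)) d <- length(image)
  if (nChannels > 1) d <- d[-length(d)]
  voxels <- as.matrix(do.call(expand.grid, lapply(d, seq_len)))
  do.call(rbind, lapply(seq_len(nrow(voxels)), function(r)
    upperClosureContributions(image, voxels[r, ], nChannels)))
}

test_that("a single voxel owns the whole closed square", {
  uc <- upperClosureContributions(matrix(7, 1, 1), c(1, 1))
  expect_equal(nrow(uc), 9)                    # 4 vertices + 4 edges + 1 square
  expect_equal(sort(table(abs(uc$delta))), sort(table(c(rep(1, 9)))))
  expect_equal(sum(uc$delta == 1), 5)
  expect_equal(sum(uc$delta == -1), 4)
  expect_equal(unique(uc$f1), 7)
  expect_equal(sum(uc$delta), 1)               # chi of a square

  expect_error(upperClosureContributions(matrix(7, 1, 1), c(2, 1)),
               "out of range")
})

test_that("an interior voxel owns 2^d cells in the Fig-9 pattern", {
  img <- matrix(5, 3, 3)
  uc <- upperClosureContributions(img, c(2, 2))
  expect_equal(nrow(uc), 4)
  expect_equal(sort(uc$delta), c(-1, -1, 1, 1)) # square, 2 edges, vertex
  expect_equal(unique(uc$f1), 5)
})

test_that("upper closures partition the complex: union equals the brute-force complex", {
  for (seed in 1:4) {
    set.seed(seed)
    img <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
    mine <- allClosures(img)
    full <- bruteCubical(img)
    expect_equal(nrow(mine), length(full$dim))
    expect_same_contribs(mine, complexContributions(full))
  }
})

test_that("the total cell count is prod(2 * m + 1)", {
  img <- array(runif(24), c(2, 3, 4))
  raw <- allClosures(img)
  expect_equal(nrow(raw), prod(2 * c(2, 3, 4) + 1))
  expect_equal(sum(raw$delta), 1)  # the full block is contractible
})

test_that("streaming equals the all-in-memory traversal bit for bit", {
  set.seed(42)
  img <- matrix(sample(0:255, 30, replace = TRUE), 5, 6)
  stream <- aggregateContributions(EulerProfiles:::.cubicalContribs(img, 1L))
  memory <- aggregateContributions(allClosures(img))
  expect_identical(stream, memory)

  rgb <- array(sample(0:255, 48, replace = TRUE), c(4, 4, 3))
  stream3 <- aggregateContributions(EulerProfiles:::.cubicalContribs(rgb, 3L))
  memory3 <- aggregateContributions(allClosures(rgb, 3L))
  expect_identical(stream3, memory3)
})

test_that("grayscale curves match the full-complex oracle", {
  # constant image: contractible at its value
  cv <- eccCubical(matrix(3, 4, 4))
  expect_equal(jumps(cv), 3)
  expect_equal(ecValues(cv), 1)

  # annulus: 8 border pixels at 0 around a bright center
  ann <- matrix(0, 3, 3); ann[2, 2] <- 255
  cv <- eccCubical(ann)
  expect_equal(ecAt(cv, c(0, 100, 255)), c(0, 0, 1))

  # two bright blobs on a dark background: 2 components at the low level
  blobs <- matrix(9, 5, 5)
  blobs[2, 2] <- 0; blobs[4, 4] <- 0
  expect_equal(ecAt(eccCubical(blobs), 0), 2)

  for (seed in 1:5) {
    set.seed(seed)
    img <- matrix(sample(0:20, 36, replace = TRUE), 6, 6)
    engine <- eccCubical(img)
    oracle <- complexToCurve(bruteCubical(img))
    expect_identical(jumps(engine), jumps(oracle))
    expect_identical(ecValues(engine), ecValues(oracle))
  }

  empty <- eccCubical(matrix(numeric(0), 0, 0))
  expect_equal(length(empty), 0)
})

test_that("1-D and 3-D images stream correctly too", {
  v <- c(3, 1, 2, 1)
  engine <- eccCubical(v)
  oracle <- complexToCurve(bruteCubical(v))
  expect_identical(jumps(engine), jumps(oracle))
  expect_identical(ecValues(engine), ecValues(oracle))

  set.seed(8)
  vol <- array(sample(0:5, 27, replace = TRUE), c(3, 3, 3))
  engine <- eccCubical(vol)
  oracle <- complexToCurve(bruteCubical(vol))
  expect_identical(jumps(engine), jumps(oracle))
  expect_identical(ecValues(engine), ecValues(oracle))
  expect_equal(ecValues(engine)[length(engine)], 1)
})

test_that("multi-channel profiles propagate per-channel minima", {
  pr <- ecpCubical(array(c(10, 20, 30), c(1, 1, 3)))
  expect_equal(profileContributions(pr), contributions(rbind(c(10, 20, 30)), 1))

  pr2 <- ecpCubical(array(5, c(2, 2, 2)))
  expect_equal(profileContributions(pr2), contributions(rbind(c(5, 5)), 1))

  for (seed in 1:4) {
    set.seed(seed)
    rgb <- array(sample(0:255, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
    engine <- ecpCubical(rgb)
    oracle <- complexToCurve(bruteCubical(rgb, nChannels = 3))
    expect_identical(engine@locations, oracle@locations)
    expect_identical(engine@deltas, oracle@deltas)
  }

  expect_error(ecpCubical(matrix(1, 3, 3), nChannels = 1), "2 channels")
})
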