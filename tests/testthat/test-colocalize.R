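# The quantification chain: channel algebra, thresholding, watershed,
# shape gating, counting, group summaries.

test_that("single-channel combination returns the rescaled channel", {
  m <- matrix(runif(64, 2, 5), 8, 8)
  img <- MultiChannelImage(list(m, matrix(0, 8, 8)))
  out <- combineChannels(img, 1L)
  expect_equal(out, (m - min(m)) / (max(m) - min(m)))
})

test_that("disjoint binary masks multiply to zero everywhere", {
  a <- matrix(0, 10, 10); a[1:5, ] <- 1
  b <- matrix(0, 10, 10); b[6:10, ] <- 1
  img <- MultiChannelImage(list(a, b))
  expect_true(all(combineChannels(img, c(1L, 2L)) == 0))
})

test_that("constant channels follow the stated rescaling convention", {
  # a positive constant channel rescales to 1, so the product keeps the
  # other channel; two positive constants give constant 1
  pos <- matrix(0.5, 6, 6)
  zero <- matrix(0, 6, 6)
  other <- matrix(seq(0, 1, length.out = 36), 6, 6)
  expect_equal(combineChannels(MultiChannelImage(list(pos, other)), c(1L, 2L)),
               other)
  expect_true(all(
    combineChannels(MultiChannelImage(list(pos, pos)), c(1L, 2L)) == 1))
  expect_true(all(
    combineChannels(MultiChannelImage(list(zero, other)), c(1L, 2L)) == 0))
})

test_that("channel selection is validated", {
  img <- MultiChannelImage(matrix(1:9 / 9, 3, 3))
  expect_error(combineChannels(img, integer(0)), "non-empty")
  expect_error(combineChannels(img, 2L), "not available")
})

test_that("otsu binarization separates a bimodal grid exactly", {
  set.seed(1)
  v <- sample(c(rep(0.1, 140), rep(0.9, 60)))
  g <- matrix(v, 10, 20)
  mask <- binarizeImage(g, QuantParams(thresholdMethod = "otsu"))
  expect_identical(mask, g == 0.9)
  # agrees with the exhaustive between-class-variance sweep oracle
  thrOracle <- sweepOtsu(v)
  expect_identical(mask, g >= thrOracle)
})

test_that("fixed and degenerate thresholding behave as specified", {
  g <- matrix(c(0.4, 0.6, 0.4, 0.6), 2, 2)
  p <- QuantParams(thresholdMethod = "fixed", fixedThreshold = 0.5)
  expect_identical(binarizeImage(g, p), g >= 0.5)
  expect_false(any(binarizeImage(matrix(0, 4, 4), QuantParams())))
  expect_error(QuantParams(thresholdMethod = "fixed"), "fixedThreshold")
})

test_that("isodata threshold splits a bimodal grid like otsu does", {
  set.seed(2)
  v <- c(rnorm(300, 0.2, 0.02), rnorm(100, 0.8, 0.02))
  g <- matrix(v, 20, 20)
  mask <- binarizeImage(g, QuantParams(thresholdMethod = "isodata"))
  expect_equal(sum(mask), 100)          # exactly the high-mode pixels
  expect_true(all(g[mask] > 0.5))
})

test_that("watershed splits touching disks and leaves isolated disks alone", {
  g <- expand.grid(r = 1:80, c = 1:80)
  single <- matrix(as.numeric(sqrt((g$r - 40)^2 + (g$c - 40)^2) <= 10), 80, 80)
  expect_equal(max(splitTouching(single, QuantParams())), 1L)
  two <- matrix(as.numeric(
    sqrt((g$r - 30)^2 + (g$c - 40)^2) <= 10 |
    sqrt((g$r - 45)^2 + (g$c - 40)^2) <= 10), 80, 80)
  expect_equal(max(splitTouching(two, QuantParams())), 2L)
  empty <- matrix(0, 16, 16)
  lab <- splitTouching(empty, QuantParams())
  expect_equal(max(lab), 0L)
  expect_equal(dim(lab), c(16L, 16L))
})

test_that("circularity closed forms hold for ideal shapes", {
  expect_equal(circularity(pi * 10^2, 2 * pi * 10), 1)        # ideal disk
  expect_equal(circularity(20^2, 4 * 20), pi / 4)             # ideal square
  expect_equal(circularity(100, 1), 1)                        # capped
})

test_that("measured circularity of digital shapes falls in the known bands", {
  disk <- digitalDisk(20)
  objDisk <- filterObjects(matrix(as.integer(disk), nrow(disk)),
                           QuantParams(minArea = 1, minCircularity = 0))
  expect_equal(nrow(objDisk), 1L)
  expect_gte(objDisk$circularity, 0.85)
  expect_lte(objDisk$circularity, 1)

  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L   # side 20
  objSq <- filterObjects(sq, QuantParams(minArea = 1, minCircularity = 0))
  expect_equal(objSq$area, 400)
  expect_lt(abs(objSq$circularity - pi / 4), 0.03)
})

test_that("size and circularity gates drop out-of-range objects", {
  lab <- matrix(0L, 20, 40)
  lab[9:11, 3:5] <- 1L         # 9 px^2 blob
  lab[5:16, 20:31] <- 2L       # 144 px^2 square
  p <- QuantParams(minArea = 20, minCircularity = 0)
  out <- filterObjects(lab, p)
  expect_equal(out$label, 2L)
  # raising min_area can only shrink the retained set (monotonicity)
  n1 <- nrow(filterObjects(lab, QuantParams(minArea = 1, minCircularity = 0)))
  n2 <- nrow(filterObjects(lab, QuantParams(minArea = 50, minCircularity = 0)))
  expect_gte(n1, n2)
})

test_that("gate monotonicity holds on a realistic segmented image", {
  sim <- simulateColocImage(20, colocFraction = 0.5, noiseSigma = 0.05,
                            touchingFraction = 0.3, seed = 11,
                            shape = c(320L, 320L))
  grid <- combineChannels(sim$image, 1L)
  lab <- splitTouching(binarizeImage(grid, QuantParams()), QuantParams())
  counts <- vapply(c(0, 0.3, 0.6, 0.9), function(mc)
    nrow(filterObjects(lab, QuantParams(minCircularity = mc))), numeric(1))
  expect_true(all(diff(counts) <= 0))
  countsA <- vapply(c(1, 50, 200, 400), function(ma)
    nrow(filterObjects(lab, QuantParams(minArea = ma, minCircularity = 0))),
    numeric(1))
  expect_true(all(diff(countsA) <= 0))
})

test_that("noise-free counting matches the pixel-overlap oracle exactly", {
  p <- QuantParams(selectedChannels = c(1L, 2L))
  for (s in c(1, 5, 9)) {
    sim <- simulateColocImage(20, colocFraction = 0.5, noiseSigma = 0,
                              shape = c(320L, 320L), seed = s)
    r <- countCoexpressing(sim$image, p)
    expect_identical(r$coexpressingCount, as.integer(truthColocCount(sim$truth)))
    expect_identical(r$referenceCount, 20L)
    expect_equal(r$fraction, 0.5)
  }
})

test_that("zero co-localization and single-channel selection behave trivially", {
  sim <- simulateColocImage(12, colocFraction = 0, noiseSigma = 0, seed = 2)
  r <- countCoexpressing(sim$image, QuantParams(selectedChannels = c(1L, 2L)))
  expect_equal(r$coexpressingCount, 0L)
  r1 <- countCoexpressing(sim$image, QuantParams(selectedChannels = 1L))
  expect_equal(r1$coexpressingCount, r1$referenceCount)
  expect_equal(r1$fraction, 1)
})

test_that("an empty reference flags the fraction as undefined", {
  img <- MultiChannelImage(list(matrix(0, 32, 32), matrix(0, 32, 32)))
  r <- countCoexpressing(img, QuantParams(selectedChannels = c(1L, 2L)))
  expect_equal(r$referenceCount, 0L)
  expect_false(r$fractionDefined)
  expect_true(is.na(r$fraction))
})

test_that("channel permutation with matching selection leaves counts unchanged", {
  sim <- simulateColocImage(15, colocFraction = 0.6, noiseSigma = 0.02,
                            seed = 4, shape = c(320L, 320L))
  ch <- channels(sim$image)
  swapped <- MultiChannelImage(list(ch[[2]], ch[[1]]))
  r1 <- countCoexpressing(sim$image, QuantParams(selectedChannels = c(1L, 2L),
                                                 referenceChannel = 1L))
  r2 <- countCoexpressing(swapped, QuantParams(selectedChannels = c(2L, 1L),
                                               referenceChannel = 2L))
  expect_identical(r1$coexpressingCount, r2$coexpressingCount)
  expect_identical(r1$referenceCount, r2$referenceCount)
})

test_that("per-animal pooling and the t-based group CI follow the formulas", {
  res <- data.frame(
    animalId = c("a1", "a1", "a2", "a3"),
    coexpressingCount = c(3, 2, 10, 6),
    referenceCount = c(6, 4, 20, 12))
  g <- estimateFractionPerGroup(res)
  expect_equal(g$perAnimal$fraction, c(0.5, 0.5, 0.5))
  expect_equal(g$mean, 0.5)
  expect_equal(g$upper - g$lower, 0)

  # frozen t-quantile example: values 1, 2, 3 -> CI (-0.4845, 4.4845)
  res2 <- data.frame(animalId = c("x", "y", "z"),
                     coexpressingCount = c(1, 2, 3),
                     referenceCount = c(1, 1, 1))
  g2 <- estimateFractionPerGroup(res2)
  expect_equal(g2$mean, 2)
  expect_equal(g2$lower, -0.48414, tolerance = 1e-4)
  expect_equal(g2$upper, 4.48414, tolerance = 1e-4)

  g1 <- estimateFractionPerGroup(res2[1, , drop = FALSE])
  expect_false(g1$ciDefined)
  expect_equal(g1$mean, 1)
  expect_error(estimateFractionPerGroup(res2[0, , drop = FALSE]), "no co")
})
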