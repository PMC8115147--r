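test_that("region entropy follows the histogram", {
  img <- matrix(0:255, 16, 16)
  all <- matrix(TRUE, 16, 16)
  expect_equal(regionEntropy(img, all), 8)            # uniform over 256 levels
  expect_equal(regionEntropy(matrix(57, 4, 4), matrix(TRUE, 4, 4)), 0)
  two <- matrix(c(10, 200), 4, 4)
  expect_equal(regionEntropy(two, matrix(TRUE, 4, 4)), 1)
  expect_error(regionEntropy(img, matrix(FALSE, 16, 16)), "empty")
})

test_that("the entropy-difference index maps to the paper-fixed bounds", {
  d <- rep(0.02, 29); d[23] <- 3e-4
  expect_identical(selectOptimalIteration(d), 35L)
  expect_identical(selectOptimalIteration(seq(0.01, 0.3, length.out = 29)), 13L)
  dTie <- rep(0.5, 29)
  expect_identical(selectOptimalIteration(dTie), 13L)  # ties -> earliest
  expect_identical(selectOptimalIteration(rep(0.1, 5), iterMin = 20L), 20L)
  expect_error(selectOptimalIteration(numeric(0)), "no entropy")
})

test_that("relative error is the normalized absolute difference in percent", {
  expect_equal(relativeError(100, 100), 0)
  expect_equal(relativeError(105, 100), 5)
  expect_equal(relativeError(0, 100), 100)
  expect_error(relativeError(10, 0), "> 0")
})

test_that("zero sweeps return the initial contour unchanged", {
  init <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
  out <- acmEvolve(matrix(100, 30, 30), init, nIter = 0)
  expect_equal(unclass(out)[, ], init)
  expect_error(acmEvolve(matrix(100, 30, 30),
                         cbind(c(5, 5, 5), c(5, 5, 5)), nIter = 1),
               "degenerate")
})

test_that("a contour grows onto a dark disk boundary within 2 px", {
  n <- 120
  Y <- matrix(seq_len(n), n, n); X <- t(Y)
  img <- ifelse(sqrt((Y - 60)^2 + (X - 60)^2) <= 20, 40, 180)
  # analytic oracle: the disk boundary is the circle of radius 20
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  init <- cbind(60 + 12 * sin(theta), 60 + 12 * cos(theta))
  out <- acmEvolve(img, init, snakeParams(points = 12L), nIter = 30,
                   field = gradientField(img, sigma = 1, scale = NULL))
  rFinal <- sqrt((out[, 1] - 60)^2 + (out[, 2] - 60)^2)
  expect_true(all(abs(rFinal - 20) <= 2))
  # greedy updates never increase the fixed energy functional
  expect_true(all(diff(attr(out, "energy")) <= 1e-9))
})


test_that("cord seeds are lateral, disjoint and mirror-symmetric", {
  ph <- generatePhantom(noiselessSpec())
  gt <- groundTruth(ph)
  seeds <- extractCordSeeds(gt$glottis)
  expect_false(any(seeds$left & gt$glottis))
  expect_false(any(seeds$right & gt$glottis))
  expect_false(any(seeds$left & seeds$right))
  # seeds lie inside the true cord bands
  expect_identical(sum(seeds$left & !gt$left), 0L)
  expect_identical(sum(seeds$right & !gt$right), 0L)
  # mirror-symmetric for the symmetric triangle
  expect_lte(abs(sum(seeds$left) - sum(seeds$right)), 2)
  expect_error(extractCordSeeds(matrix(FALSE, 5, 5)), "empty")
})

test_that("glottis segmentation recovers the phantom triangle", {
  ph <- generatePhantom(noiselessSpec())
  img <- phantomImage(ph)
  gt <- groundTruth(ph)
  mask <- segmentGlottis(img)
  expect_lte(relativeError(sum(mask), sum(gt$glottis)), 2)
  # mismatches confined to a 1-px boundary band
  kern <- EBImage::makeBrush(3, "box")
  grown <- EBImage::dilate(matrix(as.numeric(gt$glottis), nrow(img)), kern) > 0
  shrunk <- EBImage::erode(matrix(as.numeric(gt$glottis), nrow(img)), kern) > 0
  expect_true(all(mask[shrunk]))
  expect_false(any(mask[!grown]))
})

test_that("segmentGlottis picks the larger of two valid candidates", {
  img <- matrix(180, 288, 352)
  img[100:139, 50:74] <- 30    # 40 x 25 = 1000 px, aspect 0.625
  img[100:149, 200:239] <- 30  # 50 x 40 = 2000 px, aspect 0.8
  mask <- segmentGlottis(img)
  expect_identical(sum(mask), 2000L)
  expect_true(all(which(mask, arr.ind = TRUE)[, 2] >= 200))
  expect_error(segmentGlottis(matrix(c(180, 181), 288, 352)),
               "no glottal candidate")
})

test_that("adaptive iteration counts stay inside the paper-fixed bounds", {
  for (s in c(0.6, 1, 1.8)) {
    ph <- generatePhantom(quietSpec(cordScale = s))
    res <- segmentPhantom(ph)
    iters <- cordIterations(res$seg)
    expect_true(all(iters >= 13 & iters <= 41))
    expect_identical(optimalIteration(res$seg@leftTrace), res$seg@leftIters)
    expect_length(entropyDifferences(res$seg@leftTrace), 29)
  }
})

test_that("symmetric phantoms yield symmetric cord segmentations", {
  ph <- generatePhantom(quietSpec())
  res <- segmentPhantom(ph)
  expect_identical(res$seg@leftIters, res$seg@rightIters)
  masks <- cordMasks(res$seg)
  expect_false(any(masks$left & glottisMask(res$seg)))
  expect_false(any(masks$right & glottisMask(res$seg)))
  expect_false(any(masks$left & masks$right))
})

test_that("an asymmetric lesion may change one cord's count, within bounds", {
  ph <- generatePhantom(quietSpec(
    lesion = lesionSpec("cyst", side = "left", protrusionRadius = 6,
                        baseWidth = 24)))
  res <- segmentPhantom(ph)
  iters <- cordIterations(res$seg)
  expect_true(all(iters >= 13 & iters <= 41))
})

test_that("cord masks match phantom ground truth within 10% on noise-free input", {
  for (s in c(0.7, 1, 1.6)) {
    ph <- generatePhantom(quietSpec(cordScale = s))
    res <- segmentPhantom(ph)
    gt <- groundTruth(ph)
    expect_lte(relativeError(sum(res$seg@leftMask), sum(gt$left)), 10)
    expect_lte(relativeError(sum(res$seg@rightMask), sum(gt$right)), 10)
  }
})

test_that("snake energy is non-increasing on phantom cord evolutions", {
  ph <- generatePhantom(phantomSpec(seed = 13))
  res <- segmentPhantom(ph)
  for (side in c("left", "right")) {
    e <- attr(cordContours(res$seg)[[side]], "energy")
    expect_gt(length(e), 0)
    expect_true(all(diff(e) <= 1e-9))
  }
})
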