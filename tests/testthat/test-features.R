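test_that("a straight medial edge has no protrusion", {
  edge <- cbind(10:90, rep(50, 81))
  bl <- fitCordBaseline(edge)
  expect_true(all(bl[, 2] == 50))
  pg <- protrusionGeometry(edge, bl, "left")
  expect_false(pg$geometricAbnormal)
  expect_equal(pg$maxDeviation, 0)
  expect_equal(pg$protrusionWidth, 0)
  expect_true(is.na(pg$lwRatio))
})

test_that("baseline endpoints lie on the edge", {
  set.seed(8)
  edge <- cbind(1:60, 40 + round(cumsum(rnorm(60, 0, 0.4))))
  bl <- fitCordBaseline(edge)
  hits <- apply(bl, 1, function(p)
    any(edge[, 1] == p[1] & edge[, 2] == p[2]))
  expect_true(all(hits))
})

test_that("a semicircular bump measures radius, width 2r and ratio 0.5", {
  r <- 10
  rows <- 1:100
  bump <- round(sqrt(pmax(0, r^2 - (rows - 50)^2)))
  edge <- cbind(rows, 50 + bump)
  bl <- fitCordBaseline(edge)
  pg <- protrusionGeometry(edge, bl, "left")
  # oracle: brute-force point-to-line distances over the rasterized bump
  oracleMax <- max(edge[, 2] - 50)
  expect_equal(pg$maxDeviation, oracleMax)
  expect_equal(pg$maxDeviation, r, tolerance = 0.05)
  expect_equal(pg$protrusionWidth, 2 * r, tolerance = 0.15)
  expect_equal(pg$lwRatio, 0.5, tolerance = 0.1)
  expect_true(pg$geometricAbnormal)
})

test_that("sub-threshold deviations are not judged abnormal", {
  rows <- 1:100
  edge <- cbind(rows, 50 + ifelse(abs(rows - 50) <= 4, 2, 0))
  pg <- protrusionGeometry(edge, fitCordBaseline(edge), "left",
                           abnormalThreshold = 3)
  expect_false(pg$geometricAbnormal)
  expect_gt(pg$maxDeviation, 0)
})

test_that("cord grayscale standard deviation is the population s.d.", {
  img <- matrix(c(100, 150), 10, 10)
  expect_equal(cordGrayStd(img, matrix(TRUE, 10, 10)), 25)
  expect_equal(cordGrayStd(matrix(42, 5, 5), matrix(TRUE, 5, 5)), 0)
  expect_error(cordGrayStd(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("the hue feature is invariant under the compensation shift", {
  set.seed(6)
  img <- matrix(runif(400, 50, 200), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  expect_equal(cordGrayStd(img + 17.3, mask), cordGrayStd(img, mask))
})

test_that("a leukoplakia patch raises the cord's grayscale deviation", {
  base <- noiselessSpec()
  sick <- noiselessSpec(lesion = lesionSpec("leukoplakia", side = "left",
                                            patchIntensity = 245))
  for (sp in list(base, sick)) validObject(sp)
  phH <- generatePhantom(base); phL <- generatePhantom(sick)
  gtH <- groundTruth(phH); gtL <- groundTruth(phL)
  stdH <- cordGrayStd(phantomImage(phH), gtH$left)
  stdL <- cordGrayStd(phantomImage(phL), gtL$left)
  expect_gt(stdL, stdH)
})

test_that("increasing bump radius never decreases the measured deviation", {
  devs <- vapply(c(4, 6, 8, 10), function(r) {
    ph <- generatePhantom(noiselessSpec(
      lesion = lesionSpec("polyp", side = "left", protrusionRadius = r,
                          baseWidth = 2 * r)))
    ft <- extractFeatures(phantomImage(ph), groundTruth(ph)[c("left", "right")])
    ft$leftMaxDev
  }, numeric(1))
  expect_true(all(diff(devs) >= 0))
})

test_that("features are equivariant under joint translation and rotation", {
  ph <- generatePhantom(noiselessSpec(
    lesion = lesionSpec("polyp", side = "left", protrusionRadius = 8,
                        baseWidth = 14)))
  img <- phantomImage(ph)
  gt <- groundTruth(ph)
  ft <- extractFeatures(img, gt[c("left", "right")])

  shift <- function(m, dy, dx) {
    out <- matrix(if (is.logical(m)) FALSE else 0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  ftShift <- extractFeatures(shift(img, 5, 7),
                             list(left = shift(gt$left, 5, 7),
                                  right = shift(gt$right, 5, 7)))
  expect_equal(ftShift, ft)

  rot <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  # a 180-degree rotation swaps the anatomical sides
  ftRot <- extractFeatures(rot(img),
                           list(left = rot(gt$right), right = rot(gt$left)))
  expect_equal(ftRot$leftMaxDev, ft$rightMaxDev, tolerance = 0.1)
  expect_equal(ftRot$rightMaxDev, ft$leftMaxDev, tolerance = 0.1)
  expect_equal(ftRot$rightGrayStd, ft$leftGrayStd, tolerance = 1e-6)
})

test_that("extracted features are deterministic and classed correctly", {
  ph <- generatePhantom(phantomSpec(
    seed = 31, lesion = lesionSpec("polyp", side = "right",
                                   protrusionRadius = 8, baseWidth = 14)))
  res <- segmentPhantom(ph)
  f1 <- extractFeatures(res$comp, res$seg)
  f2 <- extractFeatures(res$comp, res$seg)
  expect_identical(f1, f2)
  expect_true(f1$rightAbnormal)
  expect_false(f1$leftAbnormal)
})

test_that("a healthy noiseless phantom is geometrically and chromatically quiet", {
  ph <- generatePhantom(quietSpec(seed = 2))
  res <- segmentPhantom(ph)
  ft <- extractFeatures(res$comp, res$seg)
  expect_false(ft$leftAbnormal)
  expect_false(ft$rightAbnormal)
  expect_lt(ft$leftGrayStd, 10)
  expect_lt(ft$rightGrayStd, 10)
})
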