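test_that("psnr follows its closed form", {
  a <- matrix(0, 5, 5)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, matrix(255, 5, 5)), 0)           # MSE = 255^2
  b <- a; b[] <- 1                                       # MSE = 1
  expect_equal(psnr(a, b), 20 * log10(255))
  expect_error(psnr(a, matrix(0, 4, 5)), "identical dimensions")
})

test_that("fast Otsu equals exhaustive Otsu on a two-level image", {
  img <- matrix(c(rep(50, 200), rep(200, 200)), 20, 20)
  expect_identical(as.integer(fastOtsu(img)), bruteOtsu(img))
})

test_that("fast Otsu equals exhaustive Otsu on seeded Gaussian mixtures", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- 400
    mu <- sort(runif(2, 30, 220)); p <- runif(1, 0.2, 0.8)
    v <- c(rnorm(round(p * n), mu[1], runif(1, 5, 25)),
           rnorm(n - round(p * n), mu[2], runif(1, 5, 25)))
    img <- matrix(pmin(pmax(round(v), 0), 255), 20, 20)
    if (min(img) == max(img)) next
    expect_identical(as.integer(fastOtsu(img)), bruteOtsu(img))
  }
})

test_that("fast Otsu search state respects the interval structure", {
  set.seed(11)
  img <- matrix(round(runif(400, 0, 255)), 20, 20)
  st <- attr(fastOtsu(img), "state")
  expect_lte(st$icp_b, st$icp_m)
  expect_lte(st$icp_m, st$icp_f)
  expect_equal(st$intervals[1, 1], 0)
  expect_equal(st$intervals[4, 2], 255)
  # consecutive intervals share endpoints: no gaps in [0, 255]
  expect_equal(st$intervals[1:3, 2], st$intervals[2:4, 1])
})

test_that("constant images are a degenerate input for Otsu", {
  expect_error(fastOtsu(matrix(100, 10, 10)), "degenerate")
})

test_that("labelRegions measures areas, boxes and aspect ratios", {
  m <- matrix(FALSE, 100, 100)
  m[11:40, 21:60] <- TRUE  # 30 rows x 40 cols
  r <- labelRegions(m)
  expect_identical(nrow(r), 1L)
  expect_identical(r$area, 1200L)
  expect_equal(r$aspectRatio, 40 / 30)
  expect_identical(c(r$top, r$left, r$bottom, r$right), c(11L, 21L, 40L, 60L))
  expect_equal(c(r$centroidX, r$centroidY), c(40.5, 25.5))
  expect_identical(nrow(labelRegions(matrix(FALSE, 5, 5))), 0L)
  m2 <- matrix(FALSE, 20, 20)
  m2[2:5, 2:5] <- TRUE; m2[10:13, 10:13] <- TRUE
  expect_identical(nrow(labelRegions(m2)), 2L)
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 2] <- TRUE  # diagonal chain
  r <- labelRegions(m)
  expect_identical(nrow(r), 1L)
  expect_identical(r$area, 3L)
  expect_true(all(regionMask(r, r$label[1]) == m))
})

test_that("glottal screening applies exact boundary values", {
  mk <- function(cy, ar, area)
    data.frame(label = 1L, area = area, centroidX = 100, centroidY = cy,
               top = 1L, left = 1L, bottom = 10L, right = 10L,
               aspectRatio = ar)
  keep <- function(r) nrow(screenGlottalCandidates(r)) == 1
  expect_false(keep(mk(49, 0.5, 1000)))
  expect_true(keep(mk(50, 0.5, 1000)))
  expect_true(keep(mk(240, 0.5, 1000)))
  expect_false(keep(mk(241, 0.5, 1000)))
  expect_true(keep(mk(120, 0.85, 1000)))
  expect_false(keep(mk(120, 0.86, 1000)))
  expect_false(keep(mk(120, 0.90, 1000)))
  expect_false(keep(mk(120, 0.5, 899)))
  expect_true(keep(mk(120, 0.5, 900)))
  expect_false(keep(mk(45, 0.5, 1000)))
})

test_that("screening is a pure, idempotent, order-preserving filter", {
  set.seed(3)
  regions <- data.frame(label = 1:50, area = sample(500:1500, 50),
                        centroidX = runif(50, 0, 300),
                        centroidY = runif(50, 0, 288),
                        top = 1L, left = 1L, bottom = 10L, right = 10L,
                        aspectRatio = runif(50, 0.3, 1.2))
  once <- screenGlottalCandidates(regions)
  expect_true(all(once$label %in% regions$label))
  expect_identical(once$label, sort(once$label))  # order preserved
  expect_identical(as.data.frame(screenGlottalCandidates(once)),
                   as.data.frame(once))
})

test_that("centroid bounds rescale with the frame height", {
  r <- data.frame(label = 1L, area = 1000L, centroidX = 10, centroidY = 30,
                  top = 1L, left = 1L, bottom = 5L, right = 5L,
                  aspectRatio = 0.5)
  # y = 30 fails at the 288-row reference (min 50) but passes at 144 rows
  expect_identical(nrow(screenGlottalCandidates(r, imageHeight = 288)), 0L)
  expect_identical(nrow(screenGlottalCandidates(r, imageHeight = 144)), 1L)
})

test_that("the clearest frame is the one with the largest glottal block", {
  seq <- generateSequence(phantomSpec(seed = 21), blurSchedule = c(6, 0, 6))
  sel <- selectClearestFrame(seq)
  expect_identical(sel$index, 2L)
  expect_gt(sel$area, 900)

  one <- frameSequence(frames(seq)[2])
  expect_identical(selectClearestFrame(one)$index, 1L)
})

test_that("low inter-frame PSNR discards a frame from selection", {
  base <- phantomImage(generatePhantom(phantomSpec(seed = 4)))
  set.seed(1)
  noisy <- pmin(pmax(base + matrix(rnorm(length(base), 0, 60),
                                   nrow(base)), 0), 255)
  expect_lt(psnr(noisy, base), 20)
  sel <- selectClearestFrame(frameSequence(list(base, noisy)))
  expect_identical(sel$index, 1L)
})

test_that("a sequence with no structural candidates raises an error", {
  flat <- matrix(c(rep(80, 200), rep(160, 600)), 20, 40)  # wide blocks only
  expect_error(selectClearestFrame(frameSequence(list(flat))),
               "no frame passed")
})
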