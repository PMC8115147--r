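test_that("noiseless construction paints the glottis at its nominal intensity", {
  ph <- generatePhantom(noiselessSpec())
  img <- phantomImage(ph)
  gt <- groundTruth(ph)
  expect_true(all(img[gt$glottis] == 40))
  expect_true(all(img[gt$left] == 180))
  expect_true(all(img[gt$right] == 180))
  expect_identical(gt$label, "healthy")
})

test_that("generation is deterministic for identical spec and seed", {
  spec <- phantomSpec(seed = 7, lesion = lesionSpec("tumor", textureSigma = 30))
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("invalid phantom geometry is rejected", {
  # apex above the base: not an inverted triangle
  expect_error(new("PhantomSpec", imageHeight = 100L, imageWidth = 100L,
                   glottisApex = c(50, 20), glottisBaseY = 80,
                   glottisBaseHalfWidth = 10, glottisIntensity = 40,
                   cordBandWidth = 8, cordIntensity = 180,
                   backgroundIntensity = 115, lesion = NULL,
                   illuminationOffset = 0, noiseSigma = 0, blurSigma = 0,
                   fieldRadius = c(48, 48), seed = 1L),
               "apex must lie below")
  # triangle sticking out of the frame
  expect_error(new("PhantomSpec", imageHeight = 100L, imageWidth = 100L,
                   glottisApex = c(95, 90), glottisBaseY = 10,
                   glottisBaseHalfWidth = 20, glottisIntensity = 40,
                   cordBandWidth = 8, cordIntensity = 180,
                   backgroundIntensity = 115, lesion = NULL,
                   illuminationOffset = 0, noiseSigma = 0, blurSigma = 0,
                   fieldRadius = c(48, 48), seed = 1L),
               "inside the image")
  expect_error(phantomSpec(glottisIntensity = 300), "0, 255")
})

test_that("lesion specs enforce their class-specific invariants", {
  expect_error(lesionSpec("polyp", protrusionRadius = 0, baseWidth = 10),
               "protrusionRadius")
  expect_error(lesionSpec("tumor", textureSigma = 0), "textureSigma")
  expect_error(lesionSpec("healthy"), "healthy")
  expect_error(phantomSpec(cordIntensity = 200,
                           lesion = lesionSpec("leukoplakia",
                                               patchIntensity = 190)),
               "exceed")
})

test_that("a polyp bump deviates from the straight cord edge by its radius", {
  r <- 8
  ph <- generatePhantom(noiselessSpec(
    lesion = lesionSpec("polyp", side = "left", protrusionRadius = r,
                        baseWidth = 16)))
  edge <- medialEdge(groundTruth(ph)$left, "left")
  # independent oracle: brute-force point-to-line distance against the line
  # joining the bump-free edge ends
  p1 <- edge[1, ]; p2 <- edge[nrow(edge), ]
  len <- sqrt(sum((p2 - p1)^2))
  dist <- abs((p2[1] - p1[1]) * (edge[, 2] - p1[2]) -
                (p2[2] - p1[2]) * (edge[, 1] - p1[1])) / len
  expect_equal(max(dist), r, tolerance = 0.15)
})

test_that("frame sequences honor the blur schedule contract", {
  spec <- phantomSpec(seed = 3)
  same <- generateSequence(spec, blurSchedule = c(0, 0, 0), jitter = 0)
  expect_identical(frames(same)[[1]], frames(same)[[2]])
  expect_identical(frames(same)[[2]], frames(same)[[3]])
  expect_error(generateSequence(spec, nFrames = 5, blurSchedule = c(0, 1, 2)),
               "nFrames")
  expect_error(generateSequence(spec, blurSchedule = numeric(0)), "empty")
})

test_that("the sharp frame has the largest dark glottal block", {
  seq <- generateSequence(phantomSpec(seed = 9), blurSchedule = c(6, 0, 6),
                          jitter = 0)
  # oracle: independent exhaustive Otsu + plain connected components
  areas <- vapply(frames(seq), function(f) {
    thr <- bruteOtsu(f)
    lab <- EBImage::bwlabel(matrix(as.numeric(f <= thr), nrow(f), ncol(f)))
    counts <- tabulate(as.integer(lab[lab > 0]))
    # the glottal block is dark but not the image-wide border component
    sort(counts, decreasing = TRUE)[2]
  }, numeric(1))
  expect_identical(which.max(areas), 2L)
})

test_that("the benchmark is balanced, labeled and reproducible", {
  b1 <- generateBenchmark(2, seed = 5)
  expect_length(b1$phantoms, 10)
  expect_true(all(table(b1$labels) == 2))
  expect_setequal(as.character(unique(b1$labels)), lesionLevels())
  b2 <- generateBenchmark(2, seed = 5)
  expect_identical(phantomImage(b1$phantoms[[7]]), phantomImage(b2$phantoms[[7]]))
  expect_identical(b1$manifest, b2$manifest)
  expect_error(generateBenchmark(0), "nPerClass")
  # ground-truth label matches the geometry that was generated
  for (i in seq_along(b1$phantoms))
    expect_identical(lesionLabel(b1$phantoms[[i]]),
                     as.character(b1$labels[i]))
})

test_that("benchmark output files round-trip through the manifest", {
  dir <- withr::local_tempdir()
  b <- generateBenchmark(1, seed = 2, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 5L)
  img <- readImageGray(file.path(dir, man$filename[1]))
  expect_equal(dim(img), dim(phantomImage(b$phantoms[[1]])))
  side <- jsonlite::read_json(file.path(
    dir, sub("\\.png$", ".json", man$filename[1])))
  expect_identical(side$label, man$label[1])
})
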