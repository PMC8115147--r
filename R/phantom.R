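#' @importFrom stats rnorm runif sd
NULL

# Per-row glottis boundary columns of the inverted triangle described by
# `spec`, evaluated on a full coordinate grid. Returns list(t, xL, xR, inside)
# of matrices: t is the linear taper (1 at the base row, 0 at the apex).
.glottisGeometry <- function(spec, Y, X) {
  ax <- spec@glottisApex[1]; ay <- spec@glottisApex[2]
  by <- spec@glottisBaseY; hw <- spec@glottisBaseHalfWidth
  t <- (ay - Y) / (ay - by)
  inRows <- Y >= by & Y <= ay
  xL <- ax - hw * t
  xR <- ax + hw * t
  list(t = t, xL = xL, xR = xR, inRows = inRows,
       ax = ax, ay = ay, by = by, hw = hw,
       cosTheta = (ay - by) / sqrt((ay - by)^2 + hw^2))
}

# Medial bump extents (in columns, per row) for a half-ellipse protrusion of
# perpendicular height `h` and along-edge base width `w`, centered mid-cord.
.bumpExtent <- function(Y, geo, h, w) {
  y0 <- (geo$by + geo$ay) / 2
  halfBase <- (w / 2) * geo$cosTheta    # base width measured along the edge
  u <- (Y - y0) / halfBase
  ext <- ifelse(abs(u) <= 1, (h / geo$cosTheta) * sqrt(pmax(0, 1 - u^2)), 0)
  ext
}

#' Render a synthetic laryngoscopic image with ground truth
#'
#' Deterministically renders the phantom described by a
#' \linkS4class{PhantomSpec}: elliptical endoscope field on a zero border,
#' dark inverted-triangle glottis, a pale cord band along each slanted glottis
#' edge, the optional lesion, radial illumination falloff, Gaussian noise and
#' blur. Identical spec (including seed) yields bit-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{LarynxPhantom}.
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSigma = 0, blurSigma = 0,
#'                                   illuminationOffset = 0))
#' range(phantomImage(ph)[groundTruth(ph)$glottis])
generatePhantom <- function(spec) {
  validObject(spec)
  h <- spec@imageHeight; w <- spec@imageWidth
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  geo <- .glottisGeometry(spec, Y, X)
  bw <- spec@cordBandWidth

  glottis <- geo$inRows & abs(X - geo$ax) <= spec@glottisBaseHalfWidth * geo$t
  left  <- geo$inRows & X >= geo$xL - bw & X < geo$xL
  right <- geo$inRows & X > geo$xR & X <= geo$xR + bw

  lesion <- spec@lesion
  label <- if (is.null(lesion)) "healthy" else lesion@label
  patch <- matrix(FALSE, h, w)

  withSeed(spec@seed, {
    if (!is.null(lesion)) {
      onLeft <- identical(lesion@side, "left")
      if (label %in% c("polyp", "cyst")) {
        ext <- .bumpExtent(Y, geo, lesion@protrusionRadius, lesion@baseWidth)
        bump <- if (onLeft) geo$inRows & X >= geo$xL & X < geo$xL + ext
                else geo$inRows & X <= geo$xR & X > geo$xR - ext
        if (onLeft) left <- left | bump else right <- right | bump
        glottis <- glottis & !bump
      } else if (label == "tumor" && lesion@protrusionRadius > 0) {
        # mild quasi-periodic irregularity of the medial edge
        wav <- max(8, lesion@baseWidth)
        rough <- lesion@protrusionRadius *
          pmax(0, sin(2 * pi * (Y - geo$by) / wav))
        rough[!geo$inRows] <- 0
        bump <- if (onLeft) geo$inRows & X >= geo$xL & X < geo$xL + rough
                else geo$inRows & X <= geo$xR & X > geo$xR - rough
        if (onLeft) left <- left | bump else right <- right | bump
        glottis <- glottis & !bump
      } else if (label == "leukoplakia") {
        y0 <- (geo$by + geo$ay) / 2
        t0 <- (geo$ay - y0) / (geo$ay - geo$by)
        xc <- if (onLeft) geo$ax - geo$hw * t0 - bw / 2
              else geo$ax + geo$hw * t0 + bw / 2
        rowSemi <- 0.25 * (geo$ay - geo$by); colSemi <- 0.45 * bw
        patch <- ((Y - y0) / rowSemi)^2 + ((X - xc) / colSemi)^2 <= 1
        patch <- patch & (if (onLeft) left else right)
      }
    }

    img <- matrix(spec@backgroundIntensity, h, w)
    img[left | right] <- spec@cordIntensity
    img[glottis] <- spec@glottisIntensity
    if (any(patch)) img[patch] <- lesion@patchIntensity
    if (!is.null(lesion) && label == "tumor") {
      side <- if (identical(lesion@side, "left")) left else right
      img[side] <- img[side] + rnorm(sum(side), 0, lesion@textureSigma)
    }

    cy <- h / 2; cx <- w / 2
    d2 <- ((Y - cy) / spec@fieldRadius[1])^2 + ((X - cx) / spec@fieldRadius[2])^2
    if (spec@illuminationOffset > 0)
      img <- img - spec@illuminationOffset * pmin(d2, 1)
    if (spec@noiseSigma > 0)
      img <- img + rnorm(length(img), 0, spec@noiseSigma)
    img <- gaussianBlur(img, spec@blurSigma)
    img <- round(clampGray(img))
    field <- d2 <= 1
    img[!field] <- 0

    new("LarynxPhantom", image = img,
        glottisMask = glottis & field,
        leftCordMask = left & field, rightCordMask = right & field,
        label = label, spec = spec)
  })
}

#' Generate a frame sequence from one phantom
#'
#' Renders the base phantom once, then derives each frame by a seeded
#' integer-pixel translation (zero-padded, emulating camera jitter) followed
#' by Gaussian blur of the per-frame magnitude in \code{blurSchedule}. With a
#' zero schedule and zero jitter all frames are identical. For well-separated
#' blur levels, the least-blurred frame has the largest thresholded glottal
#' area, which is what frame screening exploits.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nFrames number of frames; must equal \code{length(blurSchedule)}.
#' @param blurSchedule numeric vector of per-frame blur sigmas (pixels).
#' @param jitter maximal absolute per-frame translation (pixels).
#' @return A \linkS4class{FrameSequence}.
#' @export
#' @examples
#' seq <- generateSequence(phantomSpec(seed = 3), blurSchedule = c(6, 0, 6))
generateSequence <- function(spec, nFrames = length(blurSchedule),
                             blurSchedule, jitter = 2) {
  if (length(blurSchedule) == 0)
    stop("blurSchedule must not be empty")
  if (nFrames != length(blurSchedule))
    stop("nFrames must equal length(blurSchedule)")
  base <- phantomImage(generatePhantom(spec))
  withSeed(spec@seed + 9173L, {
    shifts <- if (jitter > 0)
      matrix(sample(seq(-jitter, jitter), 2 * nFrames, replace = TRUE),
             ncol = 2)
    else matrix(0L, nFrames, 2)
    fr <- lapply(seq_len(nFrames), function(k) {
      f <- translateImage(base, shifts[k, 1], shifts[k, 2])
      f <- gaussianBlur(f, blurSchedule[k])
      round(clampGray(f))
    })
    frameSequence(fr, source = "phantom sequence")
  })
}

# Class-conditional phantom parameter ranges for the synthetic benchmark.
# The clinical literature gives no quantitative lesion image model; these
# ranges are this package's own, chosen so the three pipeline features
# (protrusion geometry, protrusion length-to-width ratio, grayscale standard
# deviation) separate the classes on noiseless renders.
.benchmarkRanges <- function() list(
  cordScale = c(0.8, 1.3),
  glottisIntensity = c(25, 55),
  cordIntensity = c(170, 205),
  backgroundIntensity = c(95, 125),
  illuminationOffset = c(15, 30),
  polyp = list(lwRatio = c(0.45, 0.65), radius = c(6, 10)),
  cyst = list(lwRatio = c(0.15, 0.30), radius = c(4, 7)),
  leukoplakia = list(patchDelta = c(55, 80), patchMax = 252),
  tumor = list(textureSigma = c(25, 35), roughAmp = c(1.5, 2.5),
               roughWav = c(14, 22))
)

.benchmarkSpec <- function(label, itemSeed, noiseSigma, blurSigma) {
  rg <- .benchmarkRanges()
  u <- function(r) runif(1, r[1], r[2])
  withSeed(itemSeed, {
    s <- u(rg$cordScale)
    side <- sample(c("left", "right"), 1)
    cordInt <- u(rg$cordIntensity)
    lesion <- switch(label,
      healthy = NULL,
      polyp = {
        r <- u(rg$polyp$radius) * s
        lesionSpec("polyp", side, protrusionRadius = r,
                   baseWidth = r / u(rg$polyp$lwRatio))
      },
      cyst = {
        r <- u(rg$cyst$radius) * s
        lesionSpec("cyst", side, protrusionRadius = r,
                   baseWidth = r / u(rg$cyst$lwRatio))
      },
      leukoplakia = lesionSpec("leukoplakia", side,
                               patchIntensity = min(rg$leukoplakia$patchMax,
                                 cordInt + u(rg$leukoplakia$patchDelta))),
      tumor = lesionSpec("tumor", side,
                         protrusionRadius = u(rg$tumor$roughAmp) * s,
                         baseWidth = u(rg$tumor$roughWav) * s,
                         textureSigma = u(rg$tumor$textureSigma))
    )
    phantomSpec(cordScale = s,
                glottisIntensity = u(rg$glottisIntensity),
                cordIntensity = cordInt,
                backgroundIntensity = u(rg$backgroundIntensity),
                illuminationOffset = u(rg$illuminationOffset),
                noiseSigma = noiseSigma, blurSigma = blurSigma,
                lesion = lesion, seed = itemSeed)
  })
}

#' Generate a balanced labeled phantom benchmark
#'
#' Draws \code{nPerClass} phantoms per class with class-conditional parameter
#' ranges (see the methods vignette) and renders each one. Deterministic for
#' a fixed seed. Optionally writes PNG images, JSON ground-truth sidecars and
#' a CSV manifest to \code{dir}.
#'
#' @param nPerClass phantoms per class (>= 1).
#' @param seed integer master seed.
#' @param noiseSigma,blurSigma per-image perturbations (defaults: the study
#'   conditions, noise s.d. 4 gray levels and 0.8 px blur).
#' @param classes which labels to generate (default all five).
#' @param dir optional output directory.
#' @return List with \code{phantoms} (list of \linkS4class{LarynxPhantom}),
#'   \code{labels} (factor) and \code{manifest} (data.frame).
#' @export
#' @examples
#' bench <- generateBenchmark(1, seed = 7)
#' table(bench$labels)
generateBenchmark <- function(nPerClass, seed = 1L, noiseSigma = 4,
                              blurSigma = 0.8, classes = lesionLevels(),
                              dir = NULL) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  grid <- expand.grid(idx = seq_len(nPerClass), label = classes,
                      stringsAsFactors = FALSE)
  itemSeeds <- as.integer(seed) + 131L * seq_len(nrow(grid))
  phantoms <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- .benchmarkSpec(grid$label[i], itemSeeds[i], noiseSigma, blurSigma)
    phantoms[[i]] <- generatePhantom(spec)
  }
  manifest <- data.frame(
    filename = sprintf("phantom_%03d_%s.png", seq_len(nrow(grid)),
                       grid$label),
    label = grid$label, seed = itemSeeds, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(phantoms)) {
      png::writePNG(phantoms[[i]]@image / 255,
                    file.path(dir, manifest$filename[i]))
      gt <- groundTruth(phantoms[[i]])
      jsonlite::write_json(
        list(label = gt$label,
             glottis_area = sum(gt$glottis),
             left_cord_area = sum(gt$left),
             right_cord_area = sum(gt$right),
             seed = itemSeeds[i]),
        file.path(dir, sub("\\.png$", ".json", manifest$filename[i])),
        auto_unbox = TRUE)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(phantoms = phantoms,
       labels = factor(grid$label, levels = lesionLevels()),
       manifest = manifest)
}
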