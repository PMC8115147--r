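#' Laryngeal lesion labels
#'
#' The five conditions the pipeline distinguishes. \code{"healthy"} denotes a
#' cord pair without lesions; the remaining four are the lesion classes.
#'
#' @return Character vector of the five class labels.
#' @export
#' @examples
#' lesionLevels()
lesionLevels <- function() c("healthy", "polyp", "cyst", "leukoplakia", "tumor")

#' LesionSpec: parametric lesion model for the phantom generator
#'
#' Describes one lesion placed on a vocal cord of a synthetic laryngeal
#' phantom. Polyps and cysts are convex protrusions of the cord's medial
#' (glottis-facing) edge, parameterized by the perpendicular protrusion height
#' and the base width along the edge; leukoplakia is a bright mucosal patch on
#' the cord surface; tumors combine intensity heterogeneity (per-pixel texture
#' noise) with a mild irregularity of the medial edge.
#'
#' @slot label one of \code{lesionLevels()} other than \code{"healthy"}.
#' @slot side \code{"left"} or \code{"right"}: which cord carries the lesion.
#' @slot protrusionRadius numeric, pixels. Perpendicular height of the medial
#'   bump (polyp/cyst); for tumors, the amplitude of the edge irregularity.
#' @slot baseWidth numeric, pixels. Extent of the bump base along the cord
#'   edge (polyp/cyst); for tumors, the wavelength of the edge irregularity.
#' @slot patchIntensity numeric, grayscale. Leukoplakia patch level; must
#'   exceed the cord intensity.
#' @slot textureSigma numeric, grayscale. Tumor texture noise s.d.
#' @export
setClass("LesionSpec",
  representation(
    label = "character",
    side = "character",
    protrusionRadius = "numeric",
    baseWidth = "numeric",
    patchIntensity = "numeric",
    textureSigma = "numeric"
  ),
  prototype(
    label = "polyp", side = "left",
    protrusionRadius = 0, baseWidth = 0, patchIntensity = 0, textureSigma = 0
  )
)

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (!object@label %in% lesionLevels())
    msg <- c(msg, "label must be one of lesionLevels()")
  if (identical(object@label, "healthy"))
    msg <- c(msg, "a LesionSpec cannot carry label 'healthy'; use lesion = NULL")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (object@label %in% c("polyp", "cyst")) {
    if (object@protrusionRadius <= 0)
      msg <- c(msg, "polyp/cyst require protrusionRadius > 0")
    if (object@baseWidth <= 0)
      msg <- c(msg, "polyp/cyst require baseWidth > 0")
  }
  if (identical(object@label, "leukoplakia") && object@patchIntensity <= 0)
    msg <- c(msg, "leukoplakia requires patchIntensity > 0")
  if (identical(object@label, "tumor") && object@textureSigma <= 0)
    msg <- c(msg, "tumor requires textureSigma > 0")
  if (length(msg)) msg else TRUE
})

setClassUnion("LesionSpecOrNULL", members = c("LesionSpec", "NULL"))

#' @param label,side,protrusionRadius,baseWidth,patchIntensity,textureSigma
#'   see the corresponding slots.
#' @rdname LesionSpec-class
#' @return \code{lesionSpec} returns a validated \code{LesionSpec}.
#' @export
#' @examples
#' lesionSpec("polyp", side = "left", protrusionRadius = 8, baseWidth = 14)
lesionSpec <- function(label, side = "left", protrusionRadius = 0,
                       baseWidth = 0, patchIntensity = 0, textureSigma = 0) {
  new("LesionSpec", label = label, side = side,
      protrusionRadius = protrusionRadius, baseWidth = baseWidth,
      patchIntensity = patchIntensity, textureSigma = textureSigma)
}

setIsValidSpecGeometry <- function(object) {
  h <- object@imageHeight; w <- object@imageWidth
  ax <- object@glottisApex[1]; ay <- object@glottisApex[2]
  by <- object@glottisBaseY; hw <- object@glottisBaseHalfWidth
  msg <- character()
  if (ay <= by)
    msg <- c(msg, "apex must lie below the base (inverted triangle)")
  if (by < 1 || ay > h || ax - hw < 1 || ax + hw > w)
    msg <- c(msg, "glottis triangle must lie fully inside the image")
  msg
}

#' PhantomSpec: parameters of a synthetic laryngoscopic image
#'
#' Fully describes one synthetic laryngeal phantom: an elliptical endoscope
#' field of view on a black background, a dark inverted-triangle glottis
#' (base up, apex down), a pale vocal-cord band flanking each slanted glottis
#' edge, an optional lesion, a mild radial illumination falloff, additive
#' Gaussian noise and Gaussian blur. Identical spec and seed always render
#' bit-identical images.
#'
#' @slot imageHeight,imageWidth integer pixels.
#' @slot glottisApex numeric (x, y): column and row of the inferior apex.
#' @slot glottisBaseY numeric row of the (superior) triangle base.
#' @slot glottisBaseHalfWidth numeric pixels: half-width of the base.
#' @slot glottisIntensity numeric grayscale mean of the glottal space (dark).
#' @slot cordBandWidth numeric pixels: horizontal width of each cord band.
#' @slot cordIntensity numeric grayscale mean of the cords (pale).
#' @slot backgroundIntensity numeric grayscale of surrounding mucosa.
#' @slot lesion a \linkS4class{LesionSpec} or \code{NULL}.
#' @slot illuminationOffset numeric grayscale: peak radial falloff subtracted
#'   toward the field periphery (0 disables).
#' @slot noiseSigma numeric grayscale s.d. of additive noise (0 disables).
#' @slot blurSigma numeric pixels: Gaussian blur (0 disables).
#' @slot fieldRadius numeric (ry, rx): semi-axes of the elliptical field of
#'   view; pixels outside are set to grayscale 0 (the endoscope border).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(
    imageHeight = "integer", imageWidth = "integer",
    glottisApex = "numeric", glottisBaseY = "numeric",
    glottisBaseHalfWidth = "numeric",
    glottisIntensity = "numeric",
    cordBandWidth = "numeric", cordIntensity = "numeric",
    backgroundIntensity = "numeric",
    lesion = "LesionSpecOrNULL",
    illuminationOffset = "numeric", noiseSigma = "numeric",
    blurSigma = "numeric", fieldRadius = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- setIsValidSpecGeometry(object)
  ints <- c(object@glottisIntensity, object@cordIntensity,
            object@backgroundIntensity)
  if (any(ints < 0 | ints > 255))
    msg <- c(msg, "all intensity means must lie in [0, 255]")
  if (object@cordBandWidth < 1)
    msg <- c(msg, "cordBandWidth must be >= 1")
  if (any(c(object@noiseSigma, object@blurSigma) < 0))
    msg <- c(msg, "noiseSigma and blurSigma must be >= 0")
  if (!is.null(object@lesion)) {
    v <- validObject(object@lesion, test = TRUE)
    if (!isTRUE(v)) msg <- c(msg, v)
    if (identical(object@lesion@label, "leukoplakia") &&
        object@lesion@patchIntensity <= object@cordIntensity)
      msg <- c(msg, "leukoplakia patchIntensity must exceed cordIntensity")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Convenience constructor that lays out the glottis and cords from a single
#' \code{cordScale} factor emulating the endoscope's working distance (a close
#' lens magnifies the anatomy). At \code{cordScale = 1} the glottis triangle is
#' 76 px wide at the base and 116 px tall inside a 288 x 352 frame, and each
#' cord band is 16 px wide; all lengths scale linearly with \code{cordScale}.
#'
#' @param height,width image size in pixels.
#' @param cordScale unitless scale factor for the laryngeal anatomy.
#' @param glottisIntensity,cordIntensity,backgroundIntensity grayscale means.
#' @param lesion a \linkS4class{LesionSpec} or \code{NULL} (healthy).
#' @param illuminationOffset,noiseSigma,blurSigma perturbation magnitudes; see
#'   \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' spec <- phantomSpec(noiseSigma = 0, blurSigma = 0, illuminationOffset = 0)
#' ph <- generatePhantom(spec)
phantomSpec <- function(height = 288L, width = 352L, cordScale = 1,
                        glottisIntensity = 40, cordIntensity = 180,
                        backgroundIntensity = 115, lesion = NULL,
                        illuminationOffset = 20, noiseSigma = 4,
                        blurSigma = 0.8, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  cy <- round(height / 2) + 2
  gh <- round(116 * cordScale)
  new("PhantomSpec",
      imageHeight = height, imageWidth = width,
      glottisApex = c(round(width / 2), cy + floor(gh / 2)),
      glottisBaseY = cy - ceiling(gh / 2),
      glottisBaseHalfWidth = round(38 * cordScale),
      glottisIntensity = glottisIntensity,
      cordBandWidth = round(16 * cordScale),
      cordIntensity = cordIntensity,
      backgroundIntensity = backgroundIntensity,
      lesion = lesion,
      illuminationOffset = illuminationOffset,
      noiseSigma = noiseSigma, blurSigma = blurSigma,
      fieldRadius = c(round(0.485 * height), round(0.48 * width)),
      seed = as.integer(seed))
}

#' LarynxPhantom: a rendered phantom with its ground truth
#'
#' Returned by \code{\link{generatePhantom}}: the 8-bit grayscale image plus
#' the ground-truth glottis and cord masks and the lesion label implied by the
#' generating spec.
#'
#' @slot image numeric matrix, grayscale 0-255, rows = image rows.
#' @slot glottisMask,leftCordMask,rightCordMask logical matrices.
#' @slot label one of \code{lesionLevels()}.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("LarynxPhantom",
  representation(
    image = "matrix",
    glottisMask = "matrix", leftCordMask = "matrix", rightCordMask = "matrix",
    label = "character", spec = "PhantomSpec"
  )
)

#' @rdname LarynxPhantom-class
#' @export
setMethod("phantomImage", "LarynxPhantom", function(x) x@image)

#' @rdname LarynxPhantom-class
#' @export
setMethod("groundTruth", "LarynxPhantom", function(x)
  list(glottis = x@glottisMask, left = x@leftCordMask,
       right = x@rightCordMask, label = x@label))

#' @rdname LarynxPhantom-class
#' @export
setMethod("lesionLabel", "LarynxPhantom", function(x) x@label)

setMethod("show", "LarynxPhantom", function(object) {
  cat("LarynxPhantom:", nrow(object@image), "x", ncol(object@image),
      "px, label:", object@label, "\n")
  cat("  glottis area:", sum(object@glottisMask),
      "px; cord areas (L/R):", sum(object@leftCordMask), "/",
      sum(object@rightCordMask), "px\n")
})

#' FrameSequence: an ordered laryngoscopic frame stack
#'
#' All frames share a common size; order is acquisition order.
#'
#' @slot frames list of grayscale matrices (0-255).
#' @slot source character path or description.
#' @slot fps numeric frames/second (NA when unknown).
#' @export
setClass("FrameSequence",
  representation(frames = "list", source = "character", fps = "numeric"),
  prototype(source = "", fps = NA_real_)
)

setValidity("FrameSequence", function(object) {
  if (length(object@frames) == 0) return("a FrameSequence needs >= 1 frame")
  dims <- vapply(object@frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share height and width")
  TRUE
})

#' @param frames,source,fps see the corresponding slots.
#' @rdname FrameSequence-class
#' @export
frameSequence <- function(frames, source = "", fps = NA_real_)
  new("FrameSequence", frames = frames, source = source, fps = fps)

#' @rdname FrameSequence-class
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname FrameSequence-class
#' @export
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat("FrameSequence:", length(object@frames), "frame(s) of",
      d[1], "x", d[2], "px\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' ScreeningThresholds: glottal structure conditions
#'
#' The three structural filters applied to dark connected components when
#' screening for the glottal block: the component centroid's row must lie in
#' \code{[centroidYMin, centroidYMax]} (the glottis sits centrally), the
#' bounding-box aspect ratio (width/height) must not exceed
#' \code{aspectRatioMax} (the glottis is an inverted triangle, taller than
#' wide), and the pixel area must reach \code{areaMin}. The row bounds are
#' defined at a reference frame height of \code{refHeight} rows and are
#' rescaled proportionally for other frame sizes.
#'
#' @slot centroidYMin,centroidYMax numeric rows (defaults 50 and 240 at the
#'   288-row reference height).
#' @slot aspectRatioMax numeric (default 0.85).
#' @slot areaMin numeric pixels (default 900).
#' @slot refHeight numeric reference frame height (default 288).
#' @export
setClass("ScreeningThresholds",
  representation(centroidYMin = "numeric", centroidYMax = "numeric",
                 aspectRatioMax = "numeric", areaMin = "numeric",
                 refHeight = "numeric"),
  prototype(centroidYMin = 50, centroidYMax = 240, aspectRatioMax = 0.85,
            areaMin = 900, refHeight = 288)
)

setValidity("ScreeningThresholds", function(object) {
  msg <- character()
  if (object@centroidYMin >= object@centroidYMax)
    msg <- c(msg, "centroidYMin must be < centroidYMax")
  if (any(c(object@centroidYMin, object@aspectRatioMax, object@areaMin,
            object@refHeight) <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' @param centroidYMin,centroidYMax,aspectRatioMax,areaMin,refHeight see slots.
#' @rdname ScreeningThresholds-class
#' @export
#' @examples
#' screeningThresholds()
screeningThresholds <- function(centroidYMin = 50, centroidYMax = 240,
                                aspectRatioMax = 0.85, areaMin = 900,
                                refHeight = 288)
  new("ScreeningThresholds", centroidYMin = centroidYMin,
      centroidYMax = centroidYMax, aspectRatioMax = aspectRatioMax,
      areaMin = areaMin, refHeight = refHeight)

#' SnakeParams: greedy active-contour weights
#'
#' Weights of the discrete snake energy
#' \eqn{E = \sum_i w_c (d_i/d_0)^2 + w_k |v_{i-1}-2v_i+v_{i+1}|^2/d_0^2
#' - w_g G(v_i) - w_p \, s A / d_0}, where \eqn{d_i} is the spacing to the
#' previous vertex, \eqn{d_0} the mean spacing of the initial contour,
#' \eqn{G} the normalized gradient magnitude of the Gaussian-smoothed image,
#' \eqn{A} the signed (shoelace) enclosed area and \eqn{s} its sign on the
#' initial contour. The area term is an outward pressure: it carries the
#' contour across homogeneous tissue where the gradient term is silent, and
#' image edges stop the advancing front. Each sweep moves every vertex
#' greedily within a 3x3 neighborhood scaled by \code{step}; because the
#' functional is fixed and each vertex update evaluates every term it
#' participates in, total energy never increases.
#'
#' @slot wContinuity,wCurvature,wImage nonnegative weights (defaults 1, 1, 1.2).
#' @slot wPressure nonnegative outward-pressure weight (default 0.35); 0
#'   recovers the classic gradient-only snake.
#' @slot step pixels moved per candidate offset (default 1).
#' @slot points number of contour vertices (default 48, minimum 8).
#' @slot gradientSigma pixels: smoothing applied before taking gradients
#'   (default 1).
#' @slot gradientScale gray levels/pixel at which the gradient field
#'   saturates (default 12); see \code{\link{gradientField}}.
#' @export
setClass("SnakeParams",
  representation(wContinuity = "numeric", wCurvature = "numeric",
                 wImage = "numeric", wPressure = "numeric", step = "numeric",
                 points = "integer", gradientSigma = "numeric",
                 gradientScale = "numeric"),
  prototype(wContinuity = 1, wCurvature = 1, wImage = 1.2, wPressure = 0.35,
            step = 1, points = 48L, gradientSigma = 1, gradientScale = 12)
)

setValidity("SnakeParams", function(object) {
  msg <- character()
  if (any(c(object@wContinuity, object@wCurvature, object@wImage,
            object@wPressure) < 0))
    msg <- c(msg, "all weights must be >= 0")
  if (object@points < 8L) msg <- c(msg, "points must be >= 8")
  if (object@step <= 0) msg <- c(msg, "step must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param wContinuity,wCurvature,wImage,wPressure,step,points,gradientSigma,gradientScale
#'   see slots.
#' @rdname SnakeParams-class
#' @export
snakeParams <- function(wContinuity = 1, wCurvature = 1, wImage = 1.2,
                        wPressure = 0.35, step = 1, points = 48L,
                        gradientSigma = 1, gradientScale = 12)
  new("SnakeParams", wContinuity = wContinuity, wCurvature = wCurvature,
      wImage = wImage, wPressure = wPressure, step = step,
      points = as.integer(points), gradientSigma = gradientSigma,
      gradientScale = gradientScale)

#' EntropyTrace: entropy-difference record of an adaptive snake run
#'
#' For candidate index k = 1..(iterMax - iterMin + 1), the k-th entropy
#' difference compares the enclosed-region ("growth range") entropies of
#' sweeps (iterMin - 1 + k) and (iterMin + k); the selected iteration count is
#' \code{iterMin - 1 + kStar} where \code{kStar} minimizes the absolute
#' difference (ties toward smaller k). The result always lies in
#' \code{[iterMin, iterMax]}.
#'
#' @slot iterMin,iterMax integer iteration bounds (defaults 13 and 41).
#' @slot entropies numeric, bits: enclosed-region entropies for sweeps
#'   \code{iterMin .. iterMax + 1}.
#' @slot differences numeric, bits: consecutive entropy differences.
#' @slot kStar integer: argmin of \code{abs(differences)}.
#' @export
setClass("EntropyTrace",
  representation(iterMin = "integer", iterMax = "integer",
                 entropies = "numeric", differences = "numeric",
                 kStar = "integer"),
  prototype(iterMin = 13L, iterMax = 41L)
)

setValidity("EntropyTrace", function(object) {
  msg <- character()
  nCand <- object@iterMax - object@iterMin + 1L
  if (length(object@differences) != nCand)
    msg <- c(msg, sprintf("differences must have length %d", nCand))
  if (object@kStar < 1L || object@kStar > nCand)
    msg <- c(msg, "kStar out of candidate range")
  if (length(msg)) msg else TRUE
})

#' @rdname EntropyTrace-class
#' @export
setMethod("entropyDifferences", "EntropyTrace", function(x) x@differences)

#' @rdname EntropyTrace-class
#' @export
setMethod("optimalIteration", "EntropyTrace", function(x)
  x@iterMin - 1L + x@kStar)

setMethod("show", "EntropyTrace", function(object) {
  cat("EntropyTrace: bounds [", object@iterMin, ",", object@iterMax,
      "], selected iteration", optimalIteration(object),
      sprintf("(|dH| = %.5f bits)\n",
              abs(object@differences[object@kStar])))
})

#' SegmentationResult: glottis and vocal-cord segmentation
#'
#' @slot glottisMask logical matrix.
#' @slot leftContour,rightContour numeric N x 2 matrices (row, col) of the
#'   final closed cord contours.
#' @slot leftMask,rightMask logical cord masks (contour interior minus the
#'   glottis).
#' @slot leftIters,rightIters integer: adaptively selected iteration counts.
#' @slot leftTrace,rightTrace \linkS4class{EntropyTrace} objects.
#' @slot params the \linkS4class{SnakeParams} used.
#' @export
setClass("SegmentationResult",
  representation(
    glottisMask = "matrix",
    leftContour = "matrix", rightContour = "matrix",
    leftMask = "matrix", rightMask = "matrix",
    leftIters = "integer", rightIters = "integer",
    leftTrace = "EntropyTrace", rightTrace = "EntropyTrace",
    params = "SnakeParams"
  )
)

#' @rdname SegmentationResult-class
#' @export
setMethod("glottisMask", "SegmentationResult", function(x) x@glottisMask)

#' @rdname SegmentationResult-class
#' @export
setMethod("cordMasks", "SegmentationResult", function(x)
  list(left = x@leftMask, right = x@rightMask))

#' @rdname SegmentationResult-class
#' @export
setMethod("cordContours", "SegmentationResult", function(x)
  list(left = x@leftContour, right = x@rightContour))

#' @rdname SegmentationResult-class
#' @export
setMethod("cordIterations", "SegmentationResult", function(x)
  c(left = x@leftIters, right = x@rightIters))

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  cat("  glottis area:", sum(object@glottisMask), "px\n")
  cat("  cord areas (L/R):", sum(object@leftMask), "/",
      sum(object@rightMask), "px\n")
  cat("  adaptive iterations (L/R):", object@leftIters, "/",
      object@rightIters, "\n")
})

#' TreeSvmModel: decision-tree-structured SVM
#'
#' A fixed binary tree of SVM nodes: the geometry node routes cords with an
#' abnormal medial protrusion to the polyp-vs-cyst node, the remainder to the
#' hue node (healthy vs elevated grayscale variability), whose elevated branch
#' ends in the leukoplakia-vs-tumor node. Each node holds an RBF-kernel SVM
#' trained on its routed subset and the feature columns it consumes.
#'
#' @slot nodes named list of fitted node objects (internal structure).
#' @slot topology named list describing each node's children/leaves.
#' @slot classes character: the class labels covered by the leaves.
#' @slot trainingMeta list: sample counts, seed and kernel settings.
#' @export
setClass("TreeSvmModel",
  representation(nodes = "list", topology = "list", classes = "character",
                 trainingMeta = "list")
)

setValidity("TreeSvmModel", function(object) {
  kids <- unlist(lapply(object@topology, function(n) c(n$left, n$right)))
  leaves <- kids[!startsWith(kids, "node:")]
  if (!setequal(leaves, object@classes) || anyDuplicated(leaves))
    return("tree leaves must cover every class exactly once")
  TRUE
})

setMethod("show", "TreeSvmModel", function(object) {
  cat("TreeSvmModel:", length(object@nodes), "SVM nodes,",
      length(object@classes), "classes\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  m <- object@trainingMeta
  if (!is.null(m$n))
    cat("  trained on", m$n, "samples (seed", m$seed, ")\n")
})
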