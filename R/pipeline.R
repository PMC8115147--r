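#' Default pipeline configuration
#'
#' Every parameter of every stage with its default; a fully-defaulted
#' configuration is valid. Values loaded from YAML/JSON via
#' \code{\link{readRunConfig}} override these defaults; function arguments
#' override both.
#'
#' @return Nested named list of parameter blocks.
#' @export
defaultConfig <- function() list(
  version = "1",
  seed = 1L,
  preprocess = list(setValue = 125, clip = TRUE, clipLimit = 2,
                    tiles = c(8, 8), gaussianSigma = 1, kernelSize = 5),
  screening = list(centroidYMin = 50, centroidYMax = 240,
                   aspectRatioMax = 0.85, areaMin = 900, refHeight = 288,
                   psnrMin = 20),
  segmentation = list(wContinuity = 1, wCurvature = 1, wImage = 1.2,
                      wPressure = 0.35, step = 1, points = 48,
                      gradientSigma = 1, gradientScale = 12,
                      iterMin = 13, iterMax = 41, seedWidth = 5),
  features = list(abnormalThreshold = 3, refCordLength = 110,
                  deviationEps = 0.75),
  classify = list(cost = 10, gamma = 0.5, folds = 10)
)

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration
#'
#' Reads a YAML or JSON configuration file and merges it over
#' \code{\link{defaultConfig}} (file values win; unspecified parameters keep
#' their defaults).
#'
#' @param path YAML (.yml/.yaml) or JSON file; \code{NULL} returns defaults.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  .mergeConfig(cfg, user)
}

.thresholdsFromConfig <- function(cfg) {
  s <- cfg$screening
  screeningThresholds(s$centroidYMin, s$centroidYMax, s$aspectRatioMax,
                      s$areaMin, s$refHeight)
}

.snakeFromConfig <- function(cfg) {
  s <- cfg$segmentation
  snakeParams(s$wContinuity, s$wCurvature, s$wImage, s$wPressure, s$step,
              s$points, s$gradientSigma, s$gradientScale)
}

#' Run the full analysis pipeline
#'
#' Orchestrates frame screening, brightness compensation, contrast
#' enhancement, glottis and vocal-cord segmentation, feature extraction and
#' (when a model is given) lesion classification on a video frame directory,
#' a single image, or an in-memory \linkS4class{FrameSequence}. A single
#' image bypasses frame selection. Identical input, configuration and seed
#' yield an identical report.
#'
#' @param input path (frame directory or single PNG/TIFF) or a
#'   \linkS4class{FrameSequence}.
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @param model optional \linkS4class{TreeSvmModel} (or path to a saved
#'   model); without it the report carries features but no label.
#' @param verbose log applied thresholds and per-stage timings to stderr.
#' @return List report: \code{selected_frame}, \code{screening} (absent for
#'   single images), \code{segmentation} summary with entropy traces,
#'   \code{features}, \code{label} (NA without a model), \code{params} (the
#'   full configuration echo). The segmentation masks are attached in the
#'   \code{"masks"} attribute for \code{\link{writeReport}}.
#' @export
runPipeline <- function(input, config = defaultConfig(), model = NULL,
                        verbose = FALSE) {
  t0 <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  seq <- if (is(input, "FrameSequence")) input else readFrames(input)
  thresholds <- .thresholdsFromConfig(config)
  screeningBlock <- NULL
  if (nFrames(seq) > 1) {
    sel <- selectClearestFrame(seq, thresholds, config$screening$psnrMin)
    idx <- sel$index
    screeningBlock <- list(n_frames = nFrames(seq),
                           psnr_min = config$screening$psnrMin,
                           glottal_area = sel$area)
    say("screening: selected frame %d of %d (glottal area %d px)",
        idx, nFrames(seq), sel$area)
  } else idx <- 1L
  frame <- frames(seq)[[idx]]

  pp <- config$preprocess
  comp <- compensateBrightness(frame, pp$setValue, pp$clip,
                               validMask = frame > 0)
  say("compensation: shift %.2f, achieved mean %.2f",
      attr(comp, "shift"), attr(comp, "achievedMean"))
  enh <- enhanceImage(comp, pp$clipLimit, pp$tiles, pp$gaussianSigma,
                      pp$kernelSize)

  glottis <- segmentGlottis(enh, thresholds)
  seeds <- extractCordSeeds(glottis, config$segmentation$seedWidth)
  # cord contours evolve on the compensated image: the previously segmented
  # glottis is removed from it, and CLAHE's local remapping would distort
  # the gradient magnitudes the snake needs
  seg <- segmentCords(comp, glottis, .snakeFromConfig(config), seeds,
                      bounds = c(config$segmentation$iterMin,
                                 config$segmentation$iterMax))
  say("segmentation: iterations L/R = %d/%d", seg@leftIters, seg@rightIters)

  ft <- config$features
  features <- extractFeatures(comp, seg, ft$abnormalThreshold,
                              ft$refCordLength, ft$deviationEps)

  label <- NA_character_
  if (!is.null(model)) {
    if (is.character(model)) model <- loadModel(model)
    label <- as.character(classifyLesion(model, features)$label)
    say("classification: %s", label)
  }
  say("pipeline finished in %.1f s", proc.time()[3] - t0)

  report <- list(
    version = config$version,
    selected_frame = idx,
    label = label,
    features = as.list(features),
    segmentation = list(
      glottis_area = sum(glottis),
      left_cord_area = sum(seg@leftMask),
      right_cord_area = sum(seg@rightMask),
      left_iterations = seg@leftIters,
      right_iterations = seg@rightIters,
      left_entropy_differences = entropyDifferences(seg@leftTrace),
      right_entropy_differences = entropyDifferences(seg@rightTrace)),
    params = config)
  if (!is.null(screeningBlock)) report$screening <- screeningBlock
  attr(report, "masks") <- list(glottis = glottis,
                                left_cord = seg@leftMask,
                                right_cord = seg@rightMask)
  report
}
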