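#' Read a grayscale image
#'
#' Reads a PNG or TIFF image as an 8-bit grayscale matrix (0-255). RGB input
#' is converted with the standard luma weights 0.299 R + 0.587 G + 0.114 B;
#' the original RGB array is kept in the \code{"rgb"} attribute.
#'
#' @param path image file path.
#' @return Numeric matrix of grayscale values in 0-255.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext,
         " (PNG and TIFF are supported)"))
  if (length(dim(arr)) == 3) {
    rgb <- arr
    gray <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    gray <- round(gray * 255)
    attr(gray, "rgb") <- rgb
    gray
  } else round(arr * 255)
}

#' Read a frame sequence
#'
#' Accepts either a directory of numbered image frames (sorted in natural
#' numeric order, so \code{f2.png} precedes \code{f10.png}) or a single image
#' file (a sequence of length one). Video containers are not decoded; extract
#' frames to a directory first.
#'
#' @param path directory of frames or a single PNG/TIFF file.
#' @param fps optional frames/second annotation.
#' @return A \linkS4class{FrameSequence}.
#' @export
readFrames <- function(path, fps = NA_real_) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0)
      stop("no readable frames in directory: ", path)
    files <- files[naturalOrder(files)]
    fr <- lapply(files, readImageGray)
    dims <- vapply(fr, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("mixed frame sizes in ", path)
    return(frameSequence(fr, source = path, fps = fps))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mp4", "avi", "mov", "mkv"))
    stop("video decoding is not supported; extract frames to a directory ",
         "of numbered PNG/TIFF files first")
  if (!file.exists(path)) stop("cannot read: ", path)
  frameSequence(list(readImageGray(path)), source = path, fps = fps)
}

#' Write and read binary masks as single-channel PNG
#'
#' Masks are stored as 0/255 single-channel PNG and round-trip losslessly.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname writeMask
#' @return \code{readMask} returns a logical matrix.
#' @export
readMask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr > 0.5
}

#' Write and read per-image feature tables as CSV
#'
#' @param features data.frame of extracted features, one row per image.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) utils::read.csv(path)

#' Write and read a pipeline run report
#'
#' Serializes a pipeline report (selected frame, features, label, parameters)
#' to JSON; \code{masks}, when given, are written next to it as 0/255 PNGs.
#' A written report reads back to an equal structure.
#'
#' @param report named list as produced by \code{\link{runPipeline}}.
#' @param path JSON output path.
#' @param masks optional named list of logical matrices.
#' @export
writeReport <- function(report, path, masks = NULL) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(masks)) {
    stem <- sub("\\.json$", "", path)
    for (nm in names(masks))
      writeMask(masks[[nm]], paste0(stem, "_", nm, ".png"))
  }
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
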