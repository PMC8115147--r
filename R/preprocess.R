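#' Histogram-translation brightness compensation
#'
#' Shifts every pixel by \eqn{S - O_m}, where \eqn{O_m} is the mean grayscale
#' of the input and \eqn{S} the set value, so images taken at different lens
#' distances reach a common brightness level: \eqn{I(x,y) = O(x,y) + (S -
#' O_m)}. The default set value of 125 keeps typical endoscopic images from
#' over-compensating into clipping. When a validity mask is supplied, the
#' black endoscope border (grayscale 0) is excluded from \eqn{O_m} so it does
#' not bias the mean; the shift itself is applied to every pixel. When no
#' pixel clips, the output mean equals \eqn{S} exactly (the output is kept
#' numeric rather than re-quantized). Applying the compensation twice is
#' equivalent to applying it once.
#'
#' @param image numeric grayscale matrix (0-255).
#' @param setValue target mean grayscale \eqn{S} (default 125).
#' @param clip clamp the result to [0, 255] (default TRUE).
#' @param validMask optional logical matrix; TRUE pixels enter the mean.
#' @return Compensated image; the achieved mean is in attribute
#'   \code{"achievedMean"} and the applied shift in \code{"shift"}.
#' @export
#' @examples
#' img <- matrix(240, 10, 10)
#' mean(compensateBrightness(img))  # 125
compensateBrightness <- function(image, setValue = 125, clip = TRUE,
                                 validMask = NULL) {
  assertImage(image)
  if (setValue < 0 || setValue > 255) stop("setValue must lie in [0, 255]")
  om <- if (is.null(validMask)) mean(image) else {
    if (!any(validMask)) stop("validMask excludes every pixel")
    mean(image[validMask])
  }
  out <- image + (setValue - om)
  if (clip) out <- clampGray(out)
  attr(out, "shift") <- setValue - om
  attr(out, "achievedMean") <- mean(out)
  out
}

#' CLAHE contrast enhancement and Gaussian smoothing
#'
#' Applies contrast-limited adaptive histogram equalization tile-wise, then a
#' small Gaussian smoothing to suppress noise from swaying, swallowing or
#' specular saliva, before thresholding and contour evolution. A non-positive
#' \code{gaussianSigma} skips smoothing (the impulse-kernel identity limit);
#' \code{clipLimit = 0} skips CLAHE.
#'
#' @param image numeric grayscale matrix (0-255).
#' @param clipLimit CLAHE clip limit (default 2; 0 disables CLAHE).
#' @param tiles integer (rows, cols) tile grid (default c(8, 8)).
#' @param gaussianSigma smoothing sigma in pixels (default 1).
#' @param kernelSize odd Gaussian kernel size >= 3 (default 5).
#' @return Enhanced 8-bit image matrix.
#' @export
enhanceImage <- function(image, clipLimit = 2, tiles = c(8, 8),
                         gaussianSigma = 1, kernelSize = 5) {
  assertImage(image)
  if (any(tiles < 1)) stop("tile grid must be >= (1, 1)")
  if (kernelSize %% 2 == 0 || kernelSize < 3)
    stop("Gaussian kernel size must be odd and >= 3")
  out <- image / 255
  if (clipLimit > 0)
    out <- EBImage::clahe(out, nx = tiles[1], ny = tiles[2],
                          limit = clipLimit)
  if (gaussianSigma > 0) {
    k <- gaussianKernel(kernelSize, gaussianSigma)
    out <- EBImage::filter2(out, k, boundary = "replicate")
  }
  round(clampGray(as.matrix(out) * 255))
}
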