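#' Medial (glottis-facing) edge of a cord mask
#'
#' For every row occupied by the cord, the medial edge pixel is the one
#' facing the glottis: the rightmost column for the left cord, the leftmost
#' for the right cord.
#'
#' @param cordMask logical matrix.
#' @param side \code{"left"} or \code{"right"}.
#' @return N x 2 matrix of (row, col) edge points ordered by row.
#' @export
medialEdge <- function(cordMask, side = c("left", "right")) {
  side <- match.arg(side)
  rows <- which(rowSums(cordMask) > 0)
  if (length(rows) < 2) stop("degenerate cord mask")
  cols <- vapply(rows, function(y) {
    cc <- which(cordMask[y, ])
    if (side == "left") max(cc) else min(cc)
  }, numeric(1))
  cbind(row = rows, col = cols)
}

#' Fit the straight baseline along a vocal fold
#'
#' The reference line drawn along the vocal fold for the protrusion test:
#' it joins the anterior-most and posterior-most points of the cord's
#' medial edge. A small fraction of rows at either end is trimmed before
#' picking the endpoints, because the segmented cord's end caps taper where
#' the cord meets the anterior commissure and the arytenoid region and
#' would tilt the line; both endpoints always lie on the edge.
#'
#' @param edge N x 2 (row, col) medial-edge points from
#'   \code{\link{medialEdge}} (or a cord contour's medial chain).
#' @param trim fraction of edge points dropped at each end before the
#'   endpoints are taken (default 0.08).
#' @return 2 x 2 matrix: the two endpoints (row, col).
#' @export
fitCordBaseline <- function(edge, trim = 0.08) {
  if (nrow(edge) < 2) stop("degenerate contour: need >= 2 edge points")
  edge <- edge[order(edge[, 1]), , drop = FALSE]
  n <- nrow(edge)
  k <- min(floor(trim * n), (n - 2) %/% 2)
  rbind(edge[1 + k, ], edge[n - k, ])
}

# Signed perpendicular deviation of edge points from the baseline, positive
# toward the glottis (medial direction).
.medialDeviation <- function(edge, baseline, side) {
  r1 <- baseline[1, 1]; c1 <- baseline[1, 2]
  r2 <- baseline[2, 1]; c2 <- baseline[2, 2]
  len <- sqrt((r2 - r1)^2 + (c2 - c1)^2)
  cosTheta <- (r2 - r1) / len
  colOnLine <- c1 + (edge[, 1] - r1) * (c2 - c1) / (r2 - r1)
  horiz <- edge[, 2] - colOnLine
  dir <- if (side == "left") 1 else -1
  list(dev = dir * horiz * cosTheta, cosTheta = cosTheta)
}

#' Protrusion geometry of a cord's medial edge
#'
#' Measures how far the medial edge protrudes beyond the straight baseline
#' toward the glottis. \code{maxDeviation} (= the protrusion length) is the
#' maximal perpendicular deviation; the protrusion width is the extent,
#' along the baseline, of the contiguous run of points deviating beyond
#' \code{deviationEps} that contains the maximum; their ratio is the
#' length-to-width ratio separating narrow-based polyps (about 0.5 for a
#' semicircular bump) from broad-based cysts. The edge is geometrically
#' abnormal when \code{maxDeviation} exceeds \code{abnormalThreshold}.
#'
#' @param edge N x 2 medial-edge points.
#' @param baseline 2 x 2 line endpoints from \code{\link{fitCordBaseline}}.
#' @param side \code{"left"} or \code{"right"}.
#' @param abnormalThreshold pixels; deviations beyond this flag the cord as
#'   geometrically abnormal (default 3 at the reference cord length; scaled
#'   by the caller).
#' @param deviationEps pixels; rasterization tolerance below which a
#'   deviation counts as on-line (default 0.75).
#' @return List: \code{geometricAbnormal}, \code{maxDeviation},
#'   \code{protrusionLength}, \code{protrusionWidth}, \code{lwRatio}
#'   (\code{NA} when there is no protrusion).
#' @export
protrusionGeometry <- function(edge, baseline, side = c("left", "right"),
                               abnormalThreshold = 3, deviationEps = 0.75) {
  side <- match.arg(side)
  md <- .medialDeviation(edge, baseline, side)
  dev <- md$dev
  maxDev <- max(c(0, dev))
  if (maxDev <= deviationEps)
    return(list(geometricAbnormal = FALSE, maxDeviation = 0,
                protrusionLength = 0, protrusionWidth = 0, lwRatio = NA_real_))
  peak <- which.max(dev)
  above <- dev > deviationEps
  lo <- peak; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak; while (hi < length(dev) && above[hi + 1]) hi <- hi + 1
  width <- unname((edge[hi, 1] - edge[lo, 1] + 1) / md$cosTheta)
  maxDev <- unname(maxDev)
  list(geometricAbnormal = unname(maxDev > abnormalThreshold),
       maxDeviation = maxDev,
       protrusionLength = maxDev,
       protrusionWidth = width,
       lwRatio = maxDev / width)
}

#' Grayscale standard deviation of a cord region
#'
#' Population standard deviation of the (brightness-compensated) gray levels
#' under the cord mask: the hue-variability feature. Compensation shifts all
#' pixels equally, so the value is comparable across acquisitions; a bright
#' leukoplakia patch or tumor texture raises it well above a healthy cord's.
#'
#' @param image grayscale matrix (brightness-compensated).
#' @param cordMask logical matrix (nonempty).
#' @return Grayscale standard deviation.
#' @export
#' @examples
#' img <- matrix(c(100, 150), 10, 10)
#' cordGrayStd(img, matrix(TRUE, 10, 10))  # 25
cordGrayStd <- function(image, cordMask) {
  if (!any(cordMask)) stop("empty cord mask")
  v <- image[cordMask]
  sqrt(mean((v - mean(v))^2))
}

#' Extract the per-cord feature vector
#'
#' Composes the three discriminative features for both cords: the
#' geometric-abnormality flag with its protrusion measurements (from the
#' medial edge against the straight cord baseline) and the grayscale
#' standard deviation. The abnormality threshold is defined at a reference
#' cord length and scaled linearly with the measured cord extent, so the
#' judgement is lens-distance invariant. Deterministic.
#'
#' @param image grayscale matrix; use the brightness-compensated image so
#'   the hue feature is comparable across acquisitions.
#' @param segmentation a \linkS4class{SegmentationResult} (or a list with
#'   logical \code{left}/\code{right} cord masks).
#' @param abnormalThreshold pixels at the reference cord length (default 3).
#' @param refCordLength rows (default 110).
#' @param deviationEps see \code{\link{protrusionGeometry}}.
#' @param stdErodePx pixels eroded off the cord mask before the grayscale
#'   standard deviation is computed (default 2), so the hue feature reflects
#'   the cord interior rather than boundary pixels straddling the adjacent
#'   mucosa.
#' @return One-row data.frame with columns \code{<side>Abnormal},
#'   \code{<side>MaxDev}, \code{<side>Length}, \code{<side>Width},
#'   \code{<side>LwRatio}, \code{<side>GrayStd} for both sides.
#' @export
extractFeatures <- function(image, segmentation, abnormalThreshold = 3,
                            refCordLength = 110, deviationEps = 0.75,
                            stdErodePx = 2) {
  masks <- if (is(segmentation, "SegmentationResult"))
    cordMasks(segmentation) else segmentation
  one <- function(side) {
    mask <- masks[[side]]
    if (is.null(mask) || !any(mask)) stop("empty ", side, " cord mask")
    edge <- medialEdge(mask, side)
    baseline <- fitCordBaseline(edge)
    cordLen <- diff(range(edge[, 1])) + 1
    thr <- abnormalThreshold * cordLen / refCordLength
    pg <- protrusionGeometry(edge, baseline, side,
                             abnormalThreshold = thr,
                             deviationEps = deviationEps)
    stdMask <- mask
    if (stdErodePx > 0) {
      er <- EBImage::erode(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                           EBImage::makeBrush(2 * stdErodePx + 1, "box")) > 0
      if (any(er)) stdMask <- er
    }
    data.frame(Abnormal = pg$geometricAbnormal, MaxDev = pg$maxDeviation,
               Length = pg$protrusionLength, Width = pg$protrusionWidth,
               LwRatio = pg$lwRatio, GrayStd = cordGrayStd(image, stdMask))
  }
  L <- one("left"); R <- one("right")
  names(L) <- paste0("left", names(L))
  names(R) <- paste0("right", names(R))
  cbind(L, R)
}
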