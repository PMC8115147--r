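#' Peak signal-to-noise ratio between two frames
#'
#' \eqn{PSNR = 10 \log_{10}(255^2 / MSE)} in decibels; identical frames
#' return \code{Inf}. Used to reject frames whose error relative to the
#' preceding frame indicates motion or noise.
#'
#' @param frameA,frameB grayscale matrices of equal size.
#' @return Decibels (\code{Inf} for identical frames).
#' @export
#' @examples
#' psnr(matrix(10, 4, 4), matrix(11, 4, 4))
psnr <- function(frameA, frameB) {
  if (!identical(dim(frameA), dim(frameB)))
    stop("frames must have identical dimensions")
  mse <- mean((frameA - frameB)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

# Between-class variance over the full 256-bin histogram for every threshold
# t (split: levels <= t vs > t). Index i corresponds to t = i - 1.
.betweenClassVariance <- function(p) {
  levels <- 0:255
  w0 <- cumsum(p)
  mu0 <- cumsum(p * levels)
  muT <- sum(p * levels)
  s <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  s[!is.finite(s)] <- 0
  s
}

#' Fast Otsu threshold
#'
#' Restricts the Otsu between-class-variance search to four sub-intervals
#' delimited by the global mean \eqn{icp_m}, the mean of the pixels below it
#' (\eqn{icp_b}) and the mean of the pixels at or above it (\eqn{icp_f}):
#' \eqn{[0, icp_b]}, \eqn{[icp_b, icp_m]}, \eqn{[icp_m, icp_f]} and
#' \eqn{[icp_f, 255]}. The per-interval best thresholds are compared and the
#' global best returned. Because the four intervals cover the full gray
#' range, the result coincides with exhaustive Otsu while touching each bin
#' once per interval. The glottal space is darker than the mucosa, so the
#' sub-threshold class (\code{image <= threshold}) is the glottal foreground
#' downstream.
#'
#' @param image grayscale matrix with at least two distinct values.
#' @return Integer threshold in 0-255, with attribute \code{"state"} holding
#'   \code{icp_b}, \code{icp_m}, \code{icp_f}, the four search intervals and
#'   the best between-class variance.
#' @export
fastOtsu <- function(image) {
  assertImage(image)
  v <- as.vector(image)
  if (min(v) == max(v))
    stop("degenerate input: constant image has no Otsu threshold")
  icpM <- mean(v)
  icpB <- mean(v[v < icpM])
  icpF <- mean(v[v >= icpM])
  p <- tabulate(as.integer(round(clampGray(v))) + 1L, 256) / length(v)
  s <- .betweenClassVariance(p)
  intervals <- rbind(c(0, icpB), c(icpB, icpM), c(icpM, icpF), c(icpF, 255))
  best <- -Inf; bestT <- 0L
  for (i in seq_len(4)) {
    ts <- seq.int(max(0L, floor(intervals[i, 1])),
                  min(255L, ceiling(intervals[i, 2])))
    vi <- s[ts + 1L]
    j <- which.max(vi)
    if (vi[j] > best) { best <- vi[j]; bestT <- ts[j] }
  }
  structure(as.integer(bestT),
            state = list(icp_b = icpB, icp_m = icpM, icp_f = icpF,
                         intervals = intervals, best_variance = best))
}

# Merge 4-connected labels that touch diagonally into 8-connected components.
.merge8 <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  root <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Label 8-connected regions of a binary mask
#'
#' Connected-component labeling (8-connectivity) with per-region area,
#' centroid, bounding box and bounding-box aspect ratio (width/height).
#'
#' @param binary logical (or 0/1) matrix.
#' @return data.frame with columns \code{label}, \code{area},
#'   \code{centroidX}, \code{centroidY}, \code{top}, \code{left},
#'   \code{bottom}, \code{right}, \code{aspectRatio}; the label image is in
#'   attribute \code{"labels"}. An empty mask yields zero rows.
#' @export
labelRegions <- function(binary) {
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  lab <- .merge8(matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m)))
  n <- max(lab)
  if (n == 0)
    return(structure(data.frame(label = integer(), area = integer(),
                                centroidX = numeric(), centroidY = numeric(),
                                top = integer(), left = integer(),
                                bottom = integer(), right = integer(),
                                aspectRatio = numeric()),
                     labels = lab))
  idx <- which(lab > 0)
  lb <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(lb, n)
  df <- data.frame(
    label = seq_len(n),
    area = area,
    centroidX = as.vector(tapply(cols, lb, mean)),
    centroidY = as.vector(tapply(rows, lb, mean)),
    top = as.integer(tapply(rows, lb, min)),
    left = as.integer(tapply(cols, lb, min)),
    bottom = as.integer(tapply(rows, lb, max)),
    right = as.integer(tapply(cols, lb, max)))
  df$aspectRatio <- (df$right - df$left + 1) / (df$bottom - df$top + 1)
  structure(df, labels = lab)
}

#' @rdname labelRegions
#' @param regions a data.frame from \code{labelRegions}.
#' @param label region label whose mask to extract.
#' @export
regionMask <- function(regions, label) {
  lab <- attr(regions, "labels")
  if (is.null(lab)) stop("regions must carry a \"labels\" attribute")
  lab == label
}

# Rescale the centroid-row bounds to the actual frame height.
.scaleThresholds <- function(thresholds, imageHeight) {
  f <- imageHeight / thresholds@refHeight
  list(yMin = thresholds@centroidYMin * f,
       yMax = thresholds@centroidYMax * f,
       arMax = thresholds@aspectRatioMax,
       areaMin = thresholds@areaMin)
}

#' Screen dark regions for glottal candidates
#'
#' Applies the three glottal structure conditions to candidate regions (the
#' sub-threshold class of \code{\link{fastOtsu}}): keeps regions whose
#' centroid row lies within the (height-scaled) bounds, whose bounding-box
#' aspect ratio does not exceed the maximum (wide, east-west blocks such as
#' the endoscope border are dropped) and whose area reaches the minimum. A
#' pure filter: the output is a subset of the input in the original order,
#' and re-screening changes nothing.
#'
#' @param regions data.frame from \code{\link{labelRegions}}.
#' @param thresholds a \linkS4class{ScreeningThresholds}.
#' @param imageHeight frame height in rows used to rescale the centroid
#'   bounds; defaults to the thresholds' reference height (no scaling).
#' @return The retained subset of \code{regions} (labels attribute kept).
#' @export
screenGlottalCandidates <- function(regions,
                                    thresholds = screeningThresholds(),
                                    imageHeight = thresholds@refHeight) {
  th <- .scaleThresholds(thresholds, imageHeight)
  keep <- regions$centroidY >= th$yMin & regions$centroidY <= th$yMax &
    regions$aspectRatio <= th$arMax & regions$area >= th$areaMin
  structure(regions[keep, , drop = FALSE], labels = attr(regions, "labels"))
}

# Largest screened glottal candidate of one frame, or NULL.
.largestGlottalRegion <- function(frame, thresholds) {
  thr <- tryCatch(fastOtsu(frame), error = function(e) NULL)
  if (is.null(thr)) return(NULL)
  regions <- labelRegions(frame <= thr)
  cand <- screenGlottalCandidates(regions, thresholds, nrow(frame))
  if (nrow(cand) == 0) return(NULL)
  cand[which.max(cand$area), , drop = FALSE]
}

#' Select the clearest frame of a laryngoscopic sequence
#'
#' Frames whose PSNR relative to the preceding frame falls below
#' \code{psnrMin} are discarded as motion/noise (the first frame has no
#' predecessor and is always eligible). Every surviving frame contributes its
#' largest screened glottal block; the frame with the maximal glottal area is
#' the clearest (a blurred glottis thresholds to a smaller dark block). Ties
#' resolve to the earliest frame.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param thresholds a \linkS4class{ScreeningThresholds}.
#' @param psnrMin decibels; inter-frame PSNR below this discards the frame
#'   (default 20).
#' @return List with \code{index} (selected frame), \code{region} (its
#'   glottal block, one-row data.frame) and \code{area}.
#' @export
selectClearestFrame <- function(seq, thresholds = screeningThresholds(),
                                psnrMin = 20) {
  fr <- frames(seq)
  if (length(fr) == 0) stop("empty frame sequence")
  eligible <- c(TRUE, vapply(seq_along(fr)[-1], function(k)
    psnr(fr[[k]], fr[[k - 1]]) >= psnrMin, logical(1)))
  bestArea <- -Inf; bestIdx <- NA_integer_; bestRegion <- NULL
  for (k in which(eligible)) {
    reg <- .largestGlottalRegion(fr[[k]], thresholds)
    if (!is.null(reg) && reg$area > bestArea) {
      bestArea <- reg$area; bestIdx <- k; bestRegion <- reg
    }
  }
  if (is.na(bestIdx))
    stop("no frame passed the glottal structure screening")
  list(index = bestIdx, region = bestRegion, area = bestArea)
}
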