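#' Segment the glottal space
#'
#' Thresholds the (compensated, enhanced) image with \code{\link{fastOtsu}},
#' labels the dark sub-threshold class, applies the glottal structure
#' screening and returns the mask of the largest surviving region.
#'
#' @param image grayscale matrix.
#' @param thresholds a \linkS4class{ScreeningThresholds}.
#' @return Logical glottis mask.
#' @export
segmentGlottis <- function(image, thresholds = screeningThresholds()) {
  assertImage(image)
  thr <- fastOtsu(image)
  regions <- labelRegions(image <= thr)
  cand <- screenGlottalCandidates(regions, thresholds, nrow(image))
  if (nrow(cand) == 0)
    stop("no glottal candidate region found")
  regionMask(cand, cand$label[which.max(cand$area)])
}

#' Construct vocal-cord seed regions from the glottis mask
#'
#' The glottis is transected horizontally through its centroid, and a
#' vertical cut is placed through its lowest point (the maximal-row pixel,
#' the inferior apex of the inverted triangle). Between the transect row and
#' the lowest point, a thin lateral band hugging the glottis boundary on each
#' side of the vertical cut forms the left/right seed region. Seeds are
#' disjoint from the glottis and from each other, and each touches the
#' glottis boundary; for a mirror-symmetric glottis they are mirror images.
#'
#' @param glottisMask logical matrix (nonempty).
#' @param seedWidth band width in pixels (default 5).
#' @return List with logical masks \code{left} and \code{right}; the
#'   transect row and cut column are in attributes \code{"transectRow"} and
#'   \code{"cutCol"}.
#' @export
extractCordSeeds <- function(glottisMask, seedWidth = 5) {
  if (!any(glottisMask)) stop("empty glottis mask")
  idx <- which(glottisMask, arr.ind = TRUE)
  transectRow <- round(mean(idx[, 1]))
  lowestRow <- max(idx[, 1])
  cutCol <- round(mean(idx[idx[, 1] == lowestRow, 2]))
  nr <- nrow(glottisMask); nc <- ncol(glottisMask)
  left <- matrix(FALSE, nr, nc); right <- matrix(FALSE, nr, nc)
  for (y in transectRow:lowestRow) {
    cols <- which(glottisMask[y, ])
    if (length(cols) == 0) next
    lo <- min(cols); hi <- max(cols)
    lcols <- seq.int(max(1, lo - seedWidth), lo - 1)
    rcols <- seq.int(hi + 1, min(nc, hi + seedWidth))
    left[y, lcols[lcols < cutCol]] <- TRUE
    right[y, rcols[rcols > cutCol]] <- TRUE
  }
  left <- left & !glottisMask
  right <- right & !glottisMask
  structure(list(left = left, right = right),
            transectRow = transectRow, cutCol = cutCol)
}

#' Normalized gradient-magnitude field
#'
#' Gaussian-smooths the image, takes central-difference gradients and maps
#' the magnitude to [0, 1]. With \code{scale = NULL} the field is divided by
#' its global maximum; with a numeric \code{scale} (gray levels per pixel)
#' the field saturates at 1 for any gradient at or beyond that strength, so
#' every true anatomical edge holds the contour equally regardless of the
#' strongest edge in the image, while noise-level gradients stay weak.
#'
#' @param image grayscale matrix.
#' @param sigma smoothing in pixels (default 1).
#' @param scale saturation gradient in gray levels/pixel, or \code{NULL} for
#'   global-max normalization (default 12).
#' @return Matrix in [0, 1].
#' @export
gradientField <- function(image, sigma = 1, scale = 12) {
  sm <- as.matrix(gaussianBlur(image, sigma))
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2
  gy <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2
  g <- sqrt(gx^2 + gy^2)
  if (is.null(scale)) {
    mx <- max(g)
    if (mx > 0) g / mx else g
  } else pmin(g / scale, 1)
}

# Signed (shoelace) area of contour v, vertices as (row, col).
.signedArea <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  sum(v[, 2] * v[nxt, 1] - v[nxt, 2] * v[, 1]) / 2
}

# Total snake energy of contour v (N x 2, (row, col)) for diagnostics.
# curvW is the per-vertex curvature multiplier (corners may be relaxed).
.snakeEnergy <- function(v, field, params, d0, areaSign, curvW) {
  n <- nrow(v)
  prev <- c(n, seq_len(n - 1)); nxt <- c(2:n, 1)
  d <- sqrt(rowSums((v - v[prev, , drop = FALSE])^2))
  curv <- v[prev, , drop = FALSE] - 2 * v + v[nxt, , drop = FALSE]
  g <- field[cbind(pmin(pmax(round(v[, 1]), 1), nrow(field)),
                   pmin(pmax(round(v[, 2]), 1), ncol(field)))]
  sum(params@wContinuity * (d / d0)^2) +
    sum(params@wCurvature * curvW * rowSums(curv^2) / d0^2) -
    sum(params@wImage * g) -
    params@wPressure * areaSign * .signedArea(v) / d0
}

# One greedy sweep: each vertex moves to the 3x3 candidate minimizing the sum
# of all energy terms it participates in (continuity i and i+1, curvature
# i-1/i/i+1, image i, and the vertex's shoelace area contribution).
.snakeSweep <- function(v, field, params, d0, offsets, areaSign, curvW) {
  n <- nrow(v); nr <- nrow(field); nc <- ncol(field)
  wc <- params@wContinuity / d0^2
  wk <- params@wCurvature / d0^2
  wg <- params@wImage
  wp <- params@wPressure * areaSign / (2 * d0)
  for (i in seq_len(n)) {
    im1 <- if (i == 1) n else i - 1
    im2 <- if (im1 == 1) n else im1 - 1
    ip1 <- if (i == n) 1 else i + 1
    ip2 <- if (ip1 == n) 1 else ip1 + 1
    p1 <- v[im1, ]; p2 <- v[im2, ]; q1 <- v[ip1, ]; q2 <- v[ip2, ]
    cr <- pmin(pmax(v[i, 1] + offsets[, 1], 2), nr - 1)
    cc <- pmin(pmax(v[i, 2] + offsets[, 2], 2), nc - 1)
    # continuity terms i and i+1
    e <- wc * ((cr - p1[1])^2 + (cc - p1[2])^2 +
                 (q1[1] - cr)^2 + (q1[2] - cc)^2)
    # curvature terms i-1, i, i+1, each with its vertex's corner multiplier
    e <- e + wk * (
      curvW[im1] * ((p2[1] - 2 * p1[1] + cr)^2 + (p2[2] - 2 * p1[2] + cc)^2) +
      curvW[i] * ((p1[1] - 2 * cr + q1[1])^2 + (p1[2] - 2 * cc + q1[2])^2) +
      curvW[ip1] * ((cr - 2 * q1[1] + q2[1])^2 + (cc - 2 * q1[2] + q2[2])^2))
    e <- e - wg * field[cbind(cr, cc)]
    # shoelace contribution of vertex i to the signed area
    e <- e - wp * (cc * (q1[1] - p1[1]) - cr * (q1[2] - p1[2]))
    j <- which.min(e)
    # strict improvement over the current position (candidate 1) avoids drift
    if (e[j] < e[1] - 1e-12) v[i, ] <- c(cr[j], cc[j])
  }
  v
}

#' Greedy active-contour evolution
#'
#' Evolves a closed contour for exactly \code{nIter} greedy sweeps over the
#' energy \eqn{E = \sum_i w_c (d_i/d_0)^2 + w_k |v_{i-1}-2v_i+v_{i+1}|^2 /
#' d_0^2 - w_g G(v_i) - w_p s A / d_0} (see \linkS4class{SnakeParams}),
#' where \eqn{d_0} is the mean vertex spacing of the initial contour
#' (frozen, so the functional is fixed), \eqn{G} the normalized gradient
#' magnitude and \eqn{A} the signed enclosed area whose initial sign
#' \eqn{s} makes the pressure term outward. Each vertex update evaluates
#' every energy term it participates in, so the total energy is
#' non-increasing at every sweep; the per-sweep energies are returned in the
#' \code{"energy"} attribute.
#'
#' @param image grayscale matrix (ignored when \code{field} is supplied).
#' @param init N x 2 matrix of (row, col) vertices, N >= 3, inside the image.
#' @param params a \linkS4class{SnakeParams}.
#' @param nIter number of sweeps (0 returns \code{init} unchanged).
#' @param field optional precomputed \code{\link{gradientField}}.
#' @param snapshots if TRUE, keep the contour after every sweep in the
#'   \code{"snapshots"} attribute.
#' @param curvatureWeights optional per-vertex multipliers of the curvature
#'   term (anatomical corners such as the band tips may be relaxed to 0 so
#'   they stay sharp); fixed at initialization, so the energy functional is
#'   still constant during evolution.
#' @return Final contour with attributes \code{"energy"} (and optionally
#'   \code{"snapshots"}).
#' @export
acmEvolve <- function(image, init, params = snakeParams(), nIter,
                      field = NULL, snapshots = FALSE,
                      curvatureWeights = NULL) {
  if (is.null(field))
    field <- gradientField(image, params@gradientSigma, params@gradientScale)
  v <- round(init)
  if (nrow(unique(v)) < 3)
    stop("degenerate contour: fewer than 3 distinct vertices")
  if (nIter == 0) return(structure(init, energy = numeric(0)))
  n <- nrow(v)
  prev <- c(n, seq_len(n - 1))
  d0 <- mean(sqrt(rowSums((v - v[prev, , drop = FALSE])^2)))
  if (d0 == 0) stop("degenerate contour: coincident vertices")
  areaSign <- sign(.signedArea(v))
  if (areaSign == 0) areaSign <- 1
  curvW <- if (is.null(curvatureWeights)) rep(1, n) else curvatureWeights
  if (length(curvW) != n) stop("curvatureWeights must match the vertex count")
  offs <- as.matrix(expand.grid(dr = c(0, -1, 1), dc = c(0, -1, 1)))
  offs <- offs * params@step
  energies <- numeric(nIter)
  snaps <- if (snapshots) vector("list", nIter)
  for (s in seq_len(nIter)) {
    v <- .snakeSweep(v, field, params, d0, offs, areaSign, curvW)
    energies[s] <- .snakeEnergy(v, field, params, d0, areaSign, curvW)
    if (snapshots) snaps[[s]] <- v
    if (nrow(unique(v)) < 3)
      stop("contour collapsed to fewer than 3 distinct vertices")
  }
  structure(v, energy = energies, snapshots = snaps)
}

#' Shannon entropy of the gray levels under a mask
#'
#' Entropy (bits, log2) of the 256-bin grayscale histogram of the pixels
#' under the mask. Constant regions have 0 bits; a region uniform over all
#' 256 levels has 8 bits.
#'
#' @param image grayscale matrix.
#' @param mask logical matrix (nonempty).
#' @return Bits.
#' @export
regionEntropy <- function(image, mask) {
  if (!any(mask)) stop("empty mask")
  v <- as.integer(round(clampGray(image[mask])))
  p <- tabulate(v + 1L, 256)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Map entropy differences to the selected iteration count
#'
#' Candidate k compares the growth-range entropies of sweeps
#' \code{iterMin - 1 + k} and \code{iterMin + k}; the stopping rule selects
#' \code{iterMin - 1 + kStar} with \code{kStar} the (earliest) argmin of the
#' absolute differences. With the default bounds, a minimum at the 23rd
#' candidate selects iteration 35: the growth range saturates between sweeps
#' 35 and 36.
#'
#' @param differences numeric vector of consecutive entropy differences.
#' @param iterMin lower iteration bound (default 13).
#' @return Integer iteration count.
#' @export
#' @examples
#' d <- rep(0.02, 29); d[23] <- 3e-4
#' selectOptimalIteration(d)  # 35
selectOptimalIteration <- function(differences, iterMin = 13L) {
  if (length(differences) == 0) stop("no entropy differences")
  as.integer(iterMin) - 1L + which.min(abs(differences))
}

#' Adaptive iteration count by the entropy-difference rule
#'
#' Evolves the contour through \code{bounds[2] + 1} greedy sweeps, recording
#' at each sweep from \code{bounds[1]} onward the Shannon entropy of the
#' growth range (the pixels enclosed by the contour, excluding
#' \code{excludeMask}). The iteration at which consecutive entropies differ
#' least is where the growth range has saturated on the cord boundary; lens
#' distance changes the cord scale and hence where saturation occurs, which
#' is why a fixed count cannot work. The result is bounded to
#' \code{[bounds[1], bounds[2]]} by construction.
#'
#' @param image grayscale matrix.
#' @param init initial contour (N x 2).
#' @param params a \linkS4class{SnakeParams}.
#' @param bounds integer (min, max) iteration bounds, default c(13, 41).
#' @param field optional precomputed gradient field.
#' @param excludeMask optional logical matrix of pixels excluded from the
#'   growth range (previously segmented areas).
#' @param curvatureWeights passed to \code{\link{acmEvolve}}.
#' @return List with \code{optIter} (integer), \code{trace}
#'   (\linkS4class{EntropyTrace}) and \code{contour} (the contour after
#'   \code{optIter} sweeps).
#' @export
adaptiveIterations <- function(image, init, params = snakeParams(),
                               bounds = c(13L, 41L), field = NULL,
                               excludeMask = NULL, curvatureWeights = NULL) {
  iterMin <- as.integer(bounds[1]); iterMax <- as.integer(bounds[2])
  res <- acmEvolve(image, init, params, nIter = iterMax + 1L,
                   field = field, snapshots = TRUE,
                   curvatureWeights = curvatureWeights)
  snaps <- attr(res, "snapshots")
  dims <- if (is.null(field)) dim(image) else dim(field)
  ent <- vapply(iterMin:(iterMax + 1L), function(j) {
    m <- polygonMask(snaps[[j]], dims)
    if (!is.null(excludeMask)) m <- m & !excludeMask
    if (!any(m)) return(0)
    regionEntropy(image, m)
  }, numeric(1))
  differences <- diff(ent)
  kStar <- which.min(abs(differences))
  optIter <- iterMin - 1L + kStar
  trace <- new("EntropyTrace", iterMin = iterMin, iterMax = iterMax,
               entropies = ent, differences = differences,
               kStar = as.integer(kStar))
  list(optIter = optIter, trace = trace,
       contour = structure(snaps[[optIter]],
                           energy = attr(res, "energy")[seq_len(optIter)]))
}

# Initial cord contour: a thin band hugging the glottis boundary over the
# full glottis row range (medial chain 1 px lateral to the boundary, lateral
# chain `initWidth` px further out). The pressure term then grows the band
# outward until the cord's lateral edge stops the front.
.cordInitContour <- function(glottisMask, side, points, initWidth = 6) {
  idx <- which(glottisMask, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1]))
  nc <- ncol(glottisMask)
  boundary <- vapply(rows, function(y) {
    cols <- which(glottisMask[y, ])
    if (side == "left") min(cols) else max(cols)
  }, numeric(1))
  # a ragged thresholded boundary would tangle the polygon; median-smooth it
  if (length(boundary) >= 9)
    boundary <- round(stats::runmed(boundary, 9, endrule = "median"))
  half <- max(4L, as.integer(points / 2))
  pick <- unique(round(seq(1, length(rows), length.out = half)))
  sgn <- if (side == "left") -1 else 1
  medial <- cbind(rows[pick], boundary[pick] + sgn)
  lateral <- cbind(rev(rows[pick]), rev(boundary[pick]) + sgn * (1 + initWidth))
  poly <- rbind(medial, lateral)
  poly[, 2] <- pmin(pmax(poly[, 2], 2), nc - 1)
  m <- nrow(medial)
  # chain junctions: the superior and inferior tips of the band
  structure(poly, corners = c(1L, m, m + 1L, nrow(poly)))
}

#' Segment both vocal cords adaptively
#'
#' Removes the already-segmented glottis from the image (to avoid the
#' contour drifting into it), builds a lateral initial contour for each cord
#' from the glottis boundary, and evolves each side independently with the
#' entropy-difference adaptive iteration rule. The cord mask is the interior
#' of the final contour minus the glottis.
#'
#' @param image grayscale matrix (compensated and enhanced).
#' @param glottisMask logical glottis mask from \code{\link{segmentGlottis}}.
#' @param params a \linkS4class{SnakeParams}.
#' @param seeds optional seed regions from \code{\link{extractCordSeeds}}
#'   (rebuilt from the mask when missing).
#' @param bounds iteration bounds, default c(13, 41).
#' @return A \linkS4class{SegmentationResult}.
#' @export
segmentCords <- function(image, glottisMask, params = snakeParams(),
                         seeds = NULL, bounds = c(13L, 41L)) {
  assertImage(image)
  if (!any(glottisMask)) stop("empty glottis mask")
  if (is.null(seeds)) seeds <- extractCordSeeds(glottisMask)
  # The screened glottis comes from the enhanced image, whose local
  # remapping erodes the narrow apex of the triangle. Refine it to the
  # dark-class component of the ACM input image that overlaps it, so the
  # cord contours are anchored on the full glottal gap.
  darkThr <- tryCatch(fastOtsu(image), error = function(e) -Inf)
  glottisRef <- glottisMask
  if (is.finite(darkThr)) {
    reg <- labelRegions(image <= darkThr)
    if (nrow(reg) > 0) {
      lab <- attr(reg, "labels")
      overlap <- vapply(reg$label, function(l)
        sum(lab[glottisMask] == l), numeric(1))
      if (max(overlap) > 0)
        glottisRef <- glottisMask | regionMask(reg, reg$label[which.max(overlap)])
    }
  }
  img2 <- image
  img2[glottisRef] <- 0
  field <- gradientField(img2, params@gradientSigma, params@gradientScale)
  run <- function(side) {
    init <- .cordInitContour(glottisRef, side, params@points)
    cw <- rep(1, nrow(init))
    cw[attr(init, "corners")] <- 0
    adaptiveIterations(img2, init, params, bounds = bounds, field = field,
                       excludeMask = glottisRef, curvatureWeights = cw)
  }
  L <- run("left"); R <- run("right")
  # any sub-threshold (dark-class) pixels inside the contour belong to the
  # glottal gap, not to the pale cord
  maskOf <- function(res) polygonMask(res$contour, dim(image)) &
    !glottisRef & image > darkThr
  new("SegmentationResult",
      glottisMask = glottisMask,
      leftContour = unclass(L$contour), rightContour = unclass(R$contour),
      leftMask = maskOf(L), rightMask = maskOf(R),
      leftIters = L$optIter, rightIters = R$optIter,
      leftTrace = L$trace, rightTrace = R$trace,
      params = params)
}

#' Relative segmentation error
#'
#' \eqn{100 |auto - reference| / reference} in percent, the validation
#' metric comparing an automatic area measurement against a reference value.
#'
#' @param auto automatically measured pixel count.
#' @param reference reference pixel count (> 0).
#' @return Percent.
#' @export
#' @examples
#' relativeError(105, 100)  # 5
relativeError <- function(auto, reference) {
  if (any(reference <= 0)) stop("reference must be > 0")
  100 * abs(auto - reference) / reference
}
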