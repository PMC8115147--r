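# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

clampGray <- function(x) pmin(pmax(x, 0), 255)

assertImage <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop("expected a nonempty numeric matrix image")
  invisible(image)
}

# Even-odd scanline rasterization of a closed polygon given as an N x 2
# matrix of (row, col) vertices. Returns a logical mask of size `dims`.
polygonMask <- function(poly, dims) {
  nr <- dims[1]; nc <- dims[2]
  mask <- matrix(FALSE, nr, nc)
  r1 <- poly[, 1]; c1 <- poly[, 2]
  n <- nrow(poly)
  prev <- c(n, seq_len(n - 1L))
  r2 <- r1[prev]; c2 <- c1[prev]
  yLo <- max(1L, as.integer(floor(min(r1))))
  yHi <- min(nr, as.integer(ceiling(max(r1))))
  for (y in yLo:yHi) {
    cross <- ((r1 <= y) & (r2 > y)) | ((r2 <= y) & (r1 > y))
    if (!any(cross)) next
    xs <- sort(c1[cross] +
                 (y - r1[cross]) * (c2[cross] - c1[cross]) /
                 (r2[cross] - r1[cross]))
    k <- 1L
    while (k < length(xs)) {
      a <- max(1L, as.integer(ceiling(xs[k] - 1e-9)))
      b <- min(nc, as.integer(floor(xs[k + 1L] + 1e-9)))
      if (b >= a) mask[y, a:b] <- TRUE
      k <- k + 2L
    }
  }
  mask
}

# Natural (numeric-aware) sort of file names: f2 < f10.
naturalOrder <- function(x) {
  base <- basename(x)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  order(is.na(num), num, base)
}

gaussianKernel <- function(size, sigma) {
  if (size %% 2 == 0 || size < 3)
    stop("Gaussian kernel size must be odd and >= 3")
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Integer-pixel translation with zero padding (the endoscope border is 0).
translateImage <- function(image, dy, dx) {
  out <- matrix(0, nrow(image), ncol(image))
  nr <- nrow(image); nc <- ncol(image)
  srcR <- seq_len(nr) - dy; srcC <- seq_len(nc) - dx
  okR <- srcR >= 1 & srcR <= nr; okC <- srcC >= 1 & srcC <= nc
  out[which(okR), which(okC)] <- image[srcR[okR], srcC[okC]]
  out
}

gaussianBlur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  EBImage::gblur(image, sigma = sigma)
}
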