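# Shared fixtures and independent oracles, built in code.

# Noise-free, shading-free phantom: glottis pixels exactly equal the spec mean.
noiselessSpec <- function(...) {
  phantomSpec(noiseSigma = 0, blurSigma = 0, illuminationOffset = 0, ...)
}

# Noise-free phantom that keeps the deterministic radial shading (the
# entropy-based stopping rule needs some intensity variation to saturate on).
quietSpec <- function(...) {
  phantomSpec(noiseSigma = 0, blurSigma = 0, ...)
}

# The standard preprocessing + segmentation route used by several tests.
segmentPhantom <- function(ph) {
  img <- phantomImage(ph)
  comp <- compensateBrightness(img, validMask = img > 0)
  glottis <- segmentGlottis(enhanceImage(comp))
  seg <- segmentCords(comp, glottis)
  list(comp = comp, glottis = glottis, seg = seg)
}

# Independent exhaustive Otsu: between-class variance computed from first
# principles for every threshold t (class 0: values <= t, class 1: > t).
bruteOtsu <- function(image) {
  v <- as.vector(image)
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:255) {
    lo <- v[round(v) <= t]
    hi <- v[round(v) > t]
    if (length(lo) == 0 || length(hi) == 0) next
    s <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (s > best) {
      best <- s
      bestT <- t
    }
  }
  bestT
}

# Linearly separable toy feature table in the layout extractFeatures emits.
toyFeatureRow <- function(abn, maxDev, lw, std) {
  data.frame(leftAbnormal = abn, leftMaxDev = maxDev, leftLength = maxDev,
             leftWidth = ifelse(is.na(lw), 0, maxDev / max(lw, 1e-6)),
             leftLwRatio = lw, leftGrayStd = std,
             rightAbnormal = FALSE, rightMaxDev = 0, rightLength = 0,
             rightWidth = 0, rightLwRatio = NA_real_, rightGrayStd = std / 2)
}

toyFeatureSet <- function(nPerClass, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    rows <- list(); labs <- character()
    for (i in seq_len(nPerClass)) {
      rows <- c(rows, list(
        toyFeatureRow(FALSE, runif(1, 0, 1), NA, runif(1, 1, 5)),       # healthy
        toyFeatureRow(TRUE, runif(1, 6, 12), runif(1, 0.45, 0.65),
                      runif(1, 1, 5)),                                   # polyp
        toyFeatureRow(TRUE, runif(1, 5, 9), runif(1, 0.15, 0.30),
                      runif(1, 1, 5)),                                   # cyst
        toyFeatureRow(FALSE, runif(1, 0, 1), NA, runif(1, 18, 26)),      # leukoplakia
        toyFeatureRow(FALSE, runif(1, 1.5, 2.5), 0.2, runif(1, 9, 13)))) # tumor
      labs <- c(labs, c("healthy", "polyp", "cyst", "leukoplakia", "tumor"))
    }
    list(features = do.call(rbind, rows), labels = labs)
  })
}
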