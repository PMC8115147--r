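#' @importFrom e1071 svm
#' @importFrom stats predict
NULL

# Per-image classifier matrix from the per-cord feature table: the worse
# cord's protrusion geometry and the larger grayscale s.d.
.classifierMatrix <- function(features) {
  worseLeft <- features$leftMaxDev >= features$rightMaxDev
  lw <- ifelse(worseLeft, features$leftLwRatio, features$rightLwRatio)
  lw[is.na(lw)] <- 0
  cbind(maxDev = pmax(features$leftMaxDev, features$rightMaxDev),
        lwRatio = lw,
        abnormal = as.numeric(features$leftAbnormal | features$rightAbnormal),
        grayStd = pmax(features$leftGrayStd, features$rightGrayStd))
}

# Fit one binary SVM node with manual standardization (robust to
# zero-variance columns within a routed subset).
.fitNodeSvm <- function(X, y, cols, cost, gamma) {
  X <- X[, cols, drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  fit <- e1071::svm(Xs, factor(y), kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  list(fit = fit, cols = cols, center = ctr, scale = scl)
}

.predictNode <- function(node, X) {
  Xs <- scale(X[, node$cols, drop = FALSE], node$center, node$scale)
  as.character(predict(node$fit, Xs))
}

#' Train the decision-tree-structured SVM
#'
#' Builds the fixed four-node binary tree mirroring the feature logic:
#' the \emph{geometry} node separates cords with an abnormal medial
#' protrusion (polyp or cyst) from the rest; its abnormal child
#' (\emph{polypCyst}) separates polyp from cyst on the protrusion
#' length-to-width ratio and deviation; the normal child (\emph{hue})
#' separates healthy cords from those with elevated grayscale variability,
#' whose child (\emph{leukoTumor}) separates leukoplakia from tumor. Each
#' node is an RBF-kernel SVM trained on the samples its parent routes to it.
#' Deterministic given the seed.
#'
#' @param features per-cord feature table from \code{\link{extractFeatures}}
#'   (rows bound together across images).
#' @param labels factor or character vector of \code{lesionLevels()}.
#' @param cost,gamma RBF-SVM hyperparameters (defaults 10 and 0.5).
#' @param seed integer seed.
#' @return A \linkS4class{TreeSvmModel}.
#' @export
buildTree <- function(features, labels, cost = 10, gamma = 0.5, seed = 1L) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lesionLevels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  X <- .classifierMatrix(features)
  need <- function(node, classes, present) {
    missing <- setdiff(classes, present)
    if (length(missing))
      stop("training error at node '", node, "': class(es) ",
           paste(missing, collapse = ", "), " absent")
  }
  withSeed(seed, {
    geomBranch <- ifelse(labels %in% c("polyp", "cyst"),
                         "abnormal", "normal")
    need("geometry", c("abnormal", "normal"), unique(geomBranch))
    nGeom <- .fitNodeSvm(X, geomBranch, c("maxDev", "lwRatio", "abnormal"),
                         cost, gamma)
    ab <- labels %in% c("polyp", "cyst")
    need("polypCyst", c("polyp", "cyst"), unique(labels[ab]))
    nPC <- .fitNodeSvm(X[ab, , drop = FALSE], labels[ab],
                       c("lwRatio", "maxDev"), cost, gamma)
    nm <- !ab
    hueBranch <- ifelse(labels[nm] == "healthy", "healthy", "elevated")
    need("hue", c("healthy", "elevated"), unique(hueBranch))
    nHue <- .fitNodeSvm(X[nm, , drop = FALSE], hueBranch,
                        c("grayStd", "maxDev"), cost, gamma)
    lt <- labels %in% c("leukoplakia", "tumor")
    need("leukoTumor", c("leukoplakia", "tumor"), unique(labels[lt]))
    nLT <- .fitNodeSvm(X[lt, , drop = FALSE], labels[lt],
                       c("grayStd", "maxDev"), cost, gamma)
    new("TreeSvmModel",
        nodes = list(geometry = nGeom, polypCyst = nPC,
                     hue = nHue, leukoTumor = nLT),
        topology = list(
          geometry = list(left = "node:polypCyst", right = "node:hue"),
          polypCyst = list(left = "polyp", right = "cyst"),
          hue = list(left = "healthy", right = "node:leukoTumor"),
          leukoTumor = list(left = "leukoplakia", right = "tumor")),
        classes = lesionLevels(),
        trainingMeta = list(n = length(labels),
                            counts = as.list(table(labels)),
                            seed = as.integer(seed),
                            kernel = "radial", cost = cost, gamma = gamma))
  })
}

#' Classify feature vectors with a trained tree-SVM
#'
#' Routes each feature row from the root to exactly one leaf and returns the
#' leaf label plus the audit path of node decisions.
#'
#' @param model a trained \linkS4class{TreeSvmModel}.
#' @param features per-cord feature table (one or more rows).
#' @return data.frame with columns \code{label} and \code{path}.
#' @export
classifyLesion <- function(model, features) {
  if (!is(model, "TreeSvmModel") || length(model@nodes) == 0)
    stop("untrained model")
  X <- .classifierMatrix(features)
  n <- nrow(X)
  label <- character(n); path <- character(n)
  geom <- .predictNode(model@nodes$geometry, X)
  pc <- .predictNode(model@nodes$polypCyst, X)
  hue <- .predictNode(model@nodes$hue, X)
  lt <- .predictNode(model@nodes$leukoTumor, X)
  for (i in seq_len(n)) {
    if (geom[i] == "abnormal") {
      label[i] <- pc[i]
      path[i] <- paste("geometry", "polypCyst", sep = ">")
    } else if (hue[i] == "healthy") {
      label[i] <- "healthy"
      path[i] <- paste("geometry", "hue", sep = ">")
    } else {
      label[i] <- lt[i]
      path[i] <- paste("geometry", "hue", "leukoTumor", sep = ">")
    }
  }
  data.frame(label = factor(label, levels = model@classes), path = path,
             stringsAsFactors = FALSE)
}

#' @describeIn classifyLesion \code{predict} method returning the label
#'   factor only.
#' @param object a \linkS4class{TreeSvmModel}.
#' @param newdata feature table.
#' @param ... ignored.
#' @export
setMethod("predict", "TreeSvmModel", function(object, newdata, ...)
  classifyLesion(object, newdata)$label)

#' Stratified k-fold cross-validation of the tree-SVM
#'
#' Folds are stratified by class (each class's shuffled samples are dealt
#' round-robin across folds), the tree is retrained on each training split
#' and evaluated on the held-out fold. Deterministic given the seed.
#'
#' @param features per-cord feature table.
#' @param labels class labels.
#' @param k number of folds (default 10); every class must have at least
#'   \code{k} samples.
#' @param seed integer seed.
#' @param cost,gamma SVM hyperparameters passed to \code{\link{buildTree}}.
#' @return List with \code{perClass} (named recognition rates),
#'   \code{overall} (accuracy), \code{confusion} (table) and \code{folds}
#'   (the fold assignment).
#' @export
crossValidate <- function(features, labels, k = 10, seed = 1L,
                          cost = 10, gamma = 0.5) {
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("class(es) with fewer samples than folds: ",
         paste(names(counts)[counts < k], collapse = ", "))
  n <- length(labels)
  fold <- integer(n)
  withSeed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pred <- character(n)
  for (f in seq_len(k)) {
    te <- fold == f
    model <- buildTree(features[!te, , drop = FALSE], labels[!te],
                       cost = cost, gamma = gamma, seed = seed + f)
    pred[te] <- as.character(classifyLesion(
      model, features[te, , drop = FALSE])$label)
  }
  conf <- table(truth = labels, predicted = pred)
  perClass <- vapply(names(counts), function(cl)
    mean(pred[labels == cl] == cl), numeric(1))
  list(perClass = perClass, overall = mean(pred == labels),
       confusion = conf, folds = fold)
}

#' Persist and restore a trained model
#'
#' The model is archived with R's serialization; \code{loadModel} restores
#' an object giving identical predictions.
#'
#' @param model a \linkS4class{TreeSvmModel}.
#' @param path file path (conventionally \code{.rds}).
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "TreeSvmModel")) stop("not a TreeSvmModel archive")
  model
}
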