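## Iteratively trained MLP pixel classifier (one hidden layer, logistic
## activation, cross-entropy loss) over standardized multiscale features.

#' @keywords internal
.defaultHyperparameters <- function() {
  list(hiddenUnits = 32L, maxEpochs = 200L, decay = 0, maxPixelsPerClass = 10000L)
}

#' @keywords internal
.checkStackLabelPair <- function(stack, labels) {
  d <- dim(stack@features)
  if (!identical(as.integer(dim(labels)), as.integer(d[1:2]))) {
    stop("feature stack and label raster differ in spatial shape")
  }
}

#' Forward pass of a stored checkpoint
#'
#' Deterministic logistic-logistic MLP forward pass over raw (unscaled)
#' feature rows, using the standardization stored in the classifier. The
#' weight layout matches nnet's single-hidden-layer ordering (bias first per
#' unit, input-to-hidden block then hidden-to-output block).
#'
#' @param clf a [PixelClassifier-class].
#' @param x numeric matrix, one row per pixel, columns in manifest order.
#' @param iteration checkpoint index (default: selected iteration).
#' @return numeric vector of lesion probabilities.
#' @keywords internal
.forwardProbability <- function(clf, x, iteration = clf@selectedIteration) {
  ck <- clf@checkpoints[[iteration]]
  p <- length(clf@featureNames)
  h <- ck$size[2]
  xs <- sweep(sweep(x, 2L, clf@center, "-"), 2L, clf@scale, "/")
  w1 <- matrix(ck$wts[seq_len((p + 1L) * h)], nrow = p + 1L)
  w2 <- ck$wts[(p + 1L) * h + seq_len(h + 1L)]
  a1 <- 1 / (1 + exp(-(cbind(1, xs) %*% w1)))
  z2 <- cbind(1, a1) %*% w2
  as.numeric(1 / (1 + exp(-z2)))
}

#' @keywords internal
.labeledPixels <- function(stack, labels) {
  m <- featureMatrix(stack)
  idx <- which(labels != LABEL_CODES[["UNLABELED"]])
  list(
    x = m[idx, , drop = FALSE],
    y = as.integer(labels[idx] == LABEL_CODES[["LESION"]])
  )
}

#' Train the pixel classifier iteratively over the training images
#'
#' Trains a binary multilayer perceptron (one hidden layer, logistic
#' activation, cross-entropy loss, via \pkg{nnet}) on the labeled pixels of
#' the training images, saving one checkpoint after each image: checkpoint k
#' is fitted on the pooled labeled pixels of images 1..k. Unlabeled pixels
#' are excluded (sparse supervision); ignore-class pixels are the negative
#' examples. Pixel-level class imbalance is handled with inverse-frequency
#' sample weights, and features are standardized to zero mean / unit
#' variance using the training-pixel statistics of the full set, which are
#' stored in the classifier. Training is reproducible given the seed. When
#' a class exceeds \code{maxPixelsPerClass}, a seeded random subsample of
#' that size is used.
#'
#' @param stacks list of [FeatureStack-class] objects with identical
#'   manifests.
#' @param labels list of integer label rasters (see [LABEL_CODES]),
#'   congruent with the stacks.
#' @param hp hyperparameter list: \code{hiddenUnits} (32), \code{maxEpochs}
#'   (200), \code{decay} (0), \code{maxPixelsPerClass} (10000).
#' @param seed integer training seed.
#' @return A [PixelClassifier-class] with one checkpoint per training image;
#'   the last checkpoint is pre-selected until [selectClassifier()] is run.
#' @export
trainClassifier <- function(stacks, labels, hp = list(), seed = 1L) {
  if (length(stacks) < 1L || length(stacks) != length(labels)) {
    stop("need the same positive number of stacks and label rasters")
  }
  hp <- utils::modifyList(.defaultHyperparameters(), hp)
  manifest <- stacks[[1]]@featureNames
  for (i in seq_along(stacks)) {
    if (!identical(stacks[[i]]@featureNames, manifest)) {
      stop("all stacks must share one feature manifest")
    }
    .checkStackLabelPair(stacks[[i]], labels[[i]])
  }
  pix <- lapply(seq_along(stacks), function(i) {
    .labeledPixels(stacks[[i]], labels[[i]])
  })
  allY <- unlist(lapply(pix, `[[`, "y"))
  if (length(allY) == 0L || all(allY == 1L) || all(allY == 0L)) {
    stop("training annotations must contain labeled pixels of both classes")
  }
  allX <- do.call(rbind, lapply(pix, `[[`, "x"))
  center <- colMeans(allX)
  scl <- apply(allX, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  checkpoints <- vector("list", length(stacks))
  for (k in seq_along(stacks)) {
    x <- do.call(rbind, lapply(pix[seq_len(k)], `[[`, "x"))
    y <- unlist(lapply(pix[seq_len(k)], `[[`, "y"))
    set.seed(seed + k - 1L)
    keep <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      if (length(idx) > hp$maxPixelsPerClass) {
        sample(idx, hp$maxPixelsPerClass)
      } else {
        idx
      }
    }))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    if (k > 1L && (all(y == 1L) || all(y == 0L))) {
      ## early checkpoints may see only one class; carry the previous state
      checkpoints[[k]] <- checkpoints[[k - 1L]]
      checkpoints[[k]]$nTrainingImages <- k
      next
    }
    xs <- sweep(sweep(x, 2L, center, "-"), 2L, scl, "/")
    p1 <- mean(y == 1L)
    w <- ifelse(y == 1L, 0.5 / max(p1, 1e-12), 0.5 / max(1 - p1, 1e-12))
    log <- utils::capture.output(
      fit <- nnet::nnet(
        x = xs, y = y, weights = w,
        size = hp$hiddenUnits, entropy = TRUE,
        decay = hp$decay, maxit = hp$maxEpochs,
        MaxNWts = 100000L, trace = TRUE
      )
    )
    lossTrace <- suppressWarnings(
      as.numeric(sub(".*value ", "", grep("value", log, value = TRUE)))
    )
    checkpoints[[k]] <- list(
      wts = fit$wts,
      size = fit$n,           # c(inputs, hidden, outputs)
      value = fit$value,
      lossTrace = lossTrace[is.finite(lossTrace)],
      nTrainingImages = k,
      nPixels = length(y)
    )
  }
  new("PixelClassifier",
    checkpoints = checkpoints,
    selectedIteration = length(checkpoints),
    trainingSeed = as.integer(seed),
    hyperparameters = hp,
    featureNames = manifest,
    scalesPx = stacks[[1]]@scalesPx,
    center = as.numeric(center),
    scale = as.numeric(scl),
    checkpointF1 = rep(NA_real_, length(checkpoints))
  )
}

#' Pixel-level F1 score
#'
#' \code{2 TP / (2 TP + FP + FN)}; defined as 0 when there are neither
#' predicted nor true positives.
#'
#' @param pred,truth binary vectors or matrices of equal length.
#' @return scalar F1 in [0, 1].
#' @export
pixelF1 <- function(pred, truth) {
  pred <- as.integer(pred != 0)
  truth <- as.integer(truth != 0)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' @keywords internal
.selectBestIteration <- function(f1s) {
  ## argmax with ties broken toward the earliest checkpoint
  which(f1s == max(f1s))[1]
}

#' Select the deployed classifier iteration on validation images
#'
#' Scores every checkpoint by pixel-level F1 over the pooled validation
#' pixels and selects the maximiser (ties broken toward the earliest
#' checkpoint). Maximum F1 operationalizes the best compromise between
#' overall detection sensitivity and false positives, the two criteria the
#' workflow balances.
#'
#' @param clf a [PixelClassifier-class].
#' @param valStacks list of validation [FeatureStack-class] objects.
#' @param valTruth list of congruent binary ground-truth rasters.
#' @return The classifier with \code{selectedIteration} and
#'   \code{checkpointF1} filled in.
#' @export
selectClassifier <- function(clf, valStacks, valTruth) {
  stopifnot(is(clf, "PixelClassifier"))
  if (length(valStacks) < 1L || length(valStacks) != length(valTruth)) {
    stop("need the same positive number of validation stacks and truths")
  }
  xs <- list()
  ys <- list()
  for (i in seq_along(valStacks)) {
    if (!identical(valStacks[[i]]@featureNames, clf@featureNames)) {
      stop("validation stack manifest does not match the classifier")
    }
    .checkStackLabelPair(valStacks[[i]], valTruth[[i]])
    xs[[i]] <- featureMatrix(valStacks[[i]])
    ys[[i]] <- as.integer(valTruth[[i]] != 0)
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  if (all(y == 1L) || all(y == 0L)) {
    stop("validation truth must contain both classes")
  }
  f1s <- vapply(seq_along(clf@checkpoints), function(k) {
    pixelF1(as.integer(.forwardProbability(clf, x, k) > 0.5), y)
  }, numeric(1))
  clf@checkpointF1 <- f1s
  clf@selectedIteration <- as.integer(.selectBestIteration(f1s))
  validObject(clf)
  clf
}

#' Classify every pixel of a feature stack
#'
#' Applies the selected checkpoint independently to each pixel's feature
#' vector (probability threshold 0.5). Deterministic for a fixed classifier;
#' refuses stacks whose feature manifest differs from the training manifest.
#'
#' @param clf a [PixelClassifier-class].
#' @param stack a [FeatureStack-class].
#' @return integer matrix of 0/1 lesion calls with the stack's spatial
#'   shape.
#' @export
classifyPixels <- function(clf, stack) {
  stopifnot(is(clf, "PixelClassifier"), is(stack, "FeatureStack"))
  if (!identical(stack@featureNames, clf@featureNames)) {
    stop("feature manifest mismatch between stack and classifier")
  }
  d <- dim(stack@features)
  prob <- .forwardProbability(clf, featureMatrix(stack))
  matrix(as.integer(prob > 0.5), d[1], d[2])
}

## ---- persistence -------------------------------------------------------

#' Save a classifier to a JSON file
#'
#' Stores the full model: manifest (feature names and scales),
#' hyperparameters, standardization statistics, all checkpoint weight
#' vectors at full precision and the selected iteration. [loadClassifier()]
#' refuses to apply a classifier to stacks with a different manifest, and
#' classification uses the package's own forward pass, so the file is
#' self-contained.
#'
#' @param clf a [PixelClassifier-class].
#' @param path output path (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @export
saveClassifier <- function(clf, path) {
  stopifnot(is(clf, "PixelClassifier"))
  obj <- list(
    format = "xirplesion-pixel-classifier",
    version = as.character(utils::packageVersion("xirplesion")),
    featureNames = clf@featureNames,
    scalesPx = clf@scalesPx,
    hyperparameters = clf@hyperparameters,
    trainingSeed = clf@trainingSeed,
    selectedIteration = clf@selectedIteration,
    center = clf@center,
    scale = clf@scale,
    checkpointF1 = clf@checkpointF1,
    checkpoints = lapply(clf@checkpoints, function(ck) {
      list(
        wts = ck$wts, size = ck$size,
        value = ck$value, nTrainingImages = ck$nTrainingImages,
        nPixels = ck$nPixels
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [saveClassifier()]
#'
#' @param path JSON file path.
#' @return A [PixelClassifier-class].
#' @export
loadClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "xirplesion-pixel-classifier")) {
    stop("not a pixel-classifier file: ", path)
  }
  cks <- obj$checkpoints
  if (is.data.frame(cks)) {
    cks <- lapply(seq_len(nrow(cks)), function(i) as.list(cks[i, ]))
  }
  checkpoints <- lapply(cks, function(ck) {
    list(
      wts = as.numeric(unlist(ck$wts)),
      size = as.integer(unlist(ck$size)),
      value = as.numeric(ck$value),
      nTrainingImages = as.integer(ck$nTrainingImages),
      nPixels = as.integer(ck$nPixels)
    )
  })
  new("PixelClassifier",
    checkpoints = checkpoints,
    selectedIteration = as.integer(obj$selectedIteration),
    trainingSeed = as.integer(obj$trainingSeed),
    hyperparameters = lapply(obj$hyperparameters, function(v) {
      if (is.numeric(v) && v == as.integer(v)) as.integer(v) else v
    }),
    featureNames = as.character(obj$featureNames),
    scalesPx = as.numeric(obj$scalesPx),
    center = as.numeric(obj$center),
    scale = as.numeric(obj$scale),
    checkpointF1 = as.numeric(obj$checkpointF1)
  )
}
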