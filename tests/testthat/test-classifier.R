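test_that("the forward pass reproduces nnet predictions", {
  set.seed(21)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.integer(x %*% c(1, -1, 0.5) + rnorm(200, 0, 0.1) > 0)
  fit <- nnet::nnet(
    x = x, y = y, size = 4L, entropy = TRUE, maxit = 100L, trace = FALSE
  )
  clf <- new("PixelClassifier",
    checkpoints = list(list(wts = fit$wts, size = fit$n)),
    selectedIteration = 1L, trainingSeed = 0L,
    hyperparameters = list(hiddenUnits = 4L),
    featureNames = c("a", "b", "c"), scalesPx = 1,
    center = rep(0, 3), scale = rep(1, 3),
    checkpointF1 = NA_real_
  )
  ## nnet clamps its sigmoid near saturation, so agree to 1e-6 absolute
  expect_lt(
    max(abs(
      xirplesion:::.forwardProbability(clf, x) - as.numeric(predict(fit, x))
    )),
    1e-6
  )
})

test_that("well-separated clouds are learned almost perfectly", {
  train <- cloudStack(seed = 1L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 3L)
  held <- cloudStack(seed = 2L)
  pred <- classifyPixels(clf, held$stack)
  acc <- mean((pred == 1L) == held$truth)
  expect_gte(acc, 0.99)
})

test_that("one checkpoint is saved per training image and training is seeded", {
  parts <- lapply(1:4, function(s) cloudStack(n = 200L, seed = s))
  stacks <- lapply(parts, `[[`, "stack")
  labels <- lapply(parts, `[[`, "labels")
  clf1 <- trainClassifier(stacks, labels, seed = 11L)
  clf2 <- trainClassifier(stacks, labels, seed = 11L)
  expect_identical(nCheckpoints(clf1), 4L)
  probe <- cloudStack(seed = 9L)$stack
  expect_identical(classifyPixels(clf1, probe), classifyPixels(clf2, probe))
  ## a different seed gives different weights
  clf3 <- trainClassifier(stacks, labels, seed = 12L)
  expect_false(identical(clf1@checkpoints[[4]]$wts, clf3@checkpoints[[4]]$wts))
})

test_that("training loss is non-increasing across epochs", {
  train <- cloudStack(n = 300L, mu = 1, sdev = 1, seed = 4L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 5L)
  trace <- clf@checkpoints[[1]]$lossTrace
  expect_gte(length(trace), 2L)
  expect_true(all(diff(trace) <= 1e-8))
})

test_that("training rejects degenerate supervision and shape mismatches", {
  train <- cloudStack(seed = 6L)
  oneClass <- train$labels
  oneClass[oneClass == LABEL_CODES[["IGNORE"]]] <- LABEL_CODES[["UNLABELED"]]
  expect_error(
    trainClassifier(list(train$stack), list(oneClass), seed = 1L),
    "both classes"
  )
  badLab <- matrix(LABEL_CODES[["LESION"]], 3, 3)
  expect_error(
    trainClassifier(list(train$stack), list(badLab), seed = 1L),
    "shape"
  )
})

test_that("iteration selection is argmax F1 with earliest-tie breaking", {
  expect_identical(xirplesion:::.selectBestIteration(c(0.60, 0.80, 0.75)), 2L)
  expect_identical(xirplesion:::.selectBestIteration(c(0.70, 0.70)), 1L)
  expect_identical(xirplesion:::.selectBestIteration(c(0.1, 0.3, 0.3)), 2L)
})

test_that("the selected checkpoint has maximal validation F1", {
  parts <- lapply(1:3, function(s) {
    cloudStack(n = 150L, mu = 1.2, sdev = 1, seed = 20L + s)
  })
  clf <- trainClassifier(
    lapply(parts, `[[`, "stack"), lapply(parts, `[[`, "labels"),
    seed = 2L
  )
  val <- cloudStack(n = 300L, mu = 1.2, sdev = 1, seed = 30L)
  clf <- selectClassifier(clf, list(val$stack), list(val$truth))
  expect_true(all(is.finite(clf@checkpointF1)))
  expect_equal(
    clf@checkpointF1[selectedIteration(clf)], max(clf@checkpointF1)
  )
  ## replaying any checkpoint reproduces its recorded F1
  k <- selectedIteration(clf)
  pred <- as.integer(
    xirplesion:::.forwardProbability(clf, featureMatrix(val$stack), k) > 0.5
  )
  expect_equal(pixelF1(pred, val$truth), clf@checkpointF1[k])
})

test_that("selection demands both classes in the validation truth", {
  train <- cloudStack(seed = 7L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 1L)
  allNeg <- matrix(FALSE, 20, 20)
  expect_error(
    selectClassifier(clf, list(toyStack(0, 20L, 20L)), list(allNeg)),
    "both classes"
  )
})

test_that("classification is deterministic and purely per-pixel", {
  train <- cloudStack(seed = 8L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 1L)
  probe <- cloudStack(seed = 9L)$stack
  r1 <- classifyPixels(clf, probe)
  r2 <- classifyPixels(clf, probe)
  expect_identical(r1, r2)
  ## per-pixel application equals raster application (no spatial coupling)
  fm <- featureMatrix(probe)
  perPixel <- vapply(seq_len(nrow(fm)), function(i) {
    as.integer(
      xirplesion:::.forwardProbability(clf, fm[i, , drop = FALSE]) > 0.5
    )
  }, integer(1))
  expect_identical(as.integer(r1), perPixel)
})

test_that("feature-manifest mismatches are refused", {
  train <- cloudStack(seed = 10L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 1L)
  other <- toyStack(0, 6L, 6L)
  other@featureNames <- c("x_s1", "x_s2")
  expect_error(classifyPixels(clf, other), "manifest")
})

test_that("classifiers survive a save/load round trip bit-for-bit", {
  train <- cloudStack(seed = 12L)
  clf <- trainClassifier(list(train$stack), list(train$labels), seed = 4L)
  val <- cloudStack(seed = 13L)
  clf <- selectClassifier(clf, list(val$stack), list(val$truth))
  path <- withr::local_tempfile(fileext = ".json")
  saveClassifier(clf, path)
  back <- loadClassifier(path)
  expect_identical(back@featureNames, clf@featureNames)
  expect_identical(selectedIteration(back), selectedIteration(clf))
  probe <- cloudStack(seed = 14L)$stack
  expect_identical(classifyPixels(back, probe), classifyPixels(clf, probe))
  expect_error(loadClassifier(withr::local_tempfile(lines = "{}")), "classifier")
})
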