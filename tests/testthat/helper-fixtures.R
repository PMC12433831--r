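## Shared fixtures, all generated in code. Expensive objects (rendered
## tissue images, the trained classifier) are cached per session so the
## unit and acceptance tests can share them.

.fixtures <- new.env(parent = emptyenv())

#' Memoised fixture accessor
fixture <- function(key, build) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, build(), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

## A lesion-rich rendered section (training-style regime: dense lesions
## with both micro- and macrolesions represented, lesion:background
## intensity ratio 5).
tissueFixture <- function(seed, density = 30000, fieldSize = c(384L, 384L),
                          macroWeight = 0.05, ...) {
  fixture(sprintf("tissue_%d_%g_%d", seed, density, fieldSize[1]), function() {
    generateTissueImage(TissueSpec(
      fieldSizePx = fieldSize, lesionDensityPerMm2 = density,
      roiCoverage = c(0.45, 0.65), macroWeight = macroWeight, seed = seed, ...
    ))
  })
}

## Feature stack of a fixture image.
stackFixture <- function(seed, density = 30000, fieldSize = c(384L, 384L)) {
  fixture(sprintf("stack_%d_%g_%d", seed, density, fieldSize[1]), function() {
    computeFeatureStack(tissueFixture(seed, density, fieldSize)$image)
  })
}

## Classifier trained on four annotated synthetic sections (seeds 11-14)
## and selected by validation F1 on two more (seeds 21-22).
trainedClassifierFixture <- function() {
  fixture("classifier", function() {
    stacks <- list()
    labels <- list()
    for (i in seq_along(11:14)) {
      seed <- (11:14)[i]
      sim <- tissueFixture(seed)
      stacks[[i]] <- stackFixture(seed)
      ann <- annotationsFromTruth(sim$truth, sim$roi, nPerClass = 100L,
                                  seed = 100L + seed)
      labels[[i]] <- suppressWarnings(rasterizeAnnotations(ann, sim$image))
    }
    clf <- trainClassifier(stacks, labels, seed = 7L)
    selectClassifier(
      clf,
      lapply(21:22, stackFixture),
      lapply(21:22, function(s) tissueFixture(s)$truth@mask)
    )
  })
}

## Tiny hand-made feature stack: two channels, constant or supplied values.
toyStack <- function(values, nr = 8L, nc = 8L) {
  if (is.matrix(values)) {
    arr <- array(0, dim = c(nrow(values), ncol(values), 2L))
    arr[, , 1] <- values
    arr[, , 2] <- values
  } else {
    arr <- array(values, dim = c(nr, nc, 2L))
  }
  new("FeatureStack",
    features = arr, scalesPx = c(1, 2),
    featureNames = c("f_s1", "f_s2")
  )
}

## Two-Gaussian-cloud stack for separability tests: class means at -mu/+mu
## in both channels; returns the stack plus a full label raster.
cloudStack <- function(n = 400L, mu = 2, sdev = 0.5, seed = 1L) {
  set.seed(seed)
  nr <- 20L
  nc <- as.integer(ceiling(n / nr))
  npx <- nr * nc
  y <- rep(c(0L, 1L), length.out = npx)
  x1 <- rnorm(npx, ifelse(y == 1L, mu, -mu), sdev)
  x2 <- rnorm(npx, ifelse(y == 1L, mu, -mu), sdev)
  arr <- array(c(x1, x2), dim = c(nr, nc, 2L))
  stack <- new("FeatureStack",
    features = arr, scalesPx = c(1, 2),
    featureNames = c("f_s1", "f_s2")
  )
  labels <- matrix(
    ifelse(y == 1L, LABEL_CODES[["LESION"]], LABEL_CODES[["IGNORE"]]),
    nr, nc
  )
  list(stack = stack, labels = labels, truth = matrix(y == 1L, nr, nc))
}

## Brute-force flood-fill component labeling (scalar stack; independent of
## the package's frontier-BFS implementation).
floodFillOracle <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    nb <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    nb <- cbind(
      c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
      c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
    )
  }
  cur <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc] || lab[rr, cc] != 0L) next
      cur <- cur + 1L
      todo <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(todo) > 0L) {
        p <- todo[[length(todo)]]
        todo[[length(todo)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          r2 <- p[1] + nb[k, 1]
          c2 <- p[2] + nb[k, 2]
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            todo[[length(todo) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

## Canonical relabeling by first occurrence, for comparing labelings.
canonicalLabels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  out <- lab
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

## Direct (non-separable) 2D correlation with reflect padding, as an
## independent oracle for the feature filters.
directConv2 <- function(m, k2d) {
  nr <- nrow(m); nc <- ncol(m)
  rk <- (nrow(k2d) - 1L) %/% 2L
  ck <- (ncol(k2d) - 1L) %/% 2L
  refl <- function(i, n) {
    period <- 2L * n
    mm <- (i - 1L) %% period
    ifelse(mm < n, mm + 1L, period - mm)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      acc <- 0
      for (dr in -rk:rk) {
        for (dc in -ck:ck) {
          acc <- acc + k2d[dr + rk + 1L, dc + ck + 1L] *
            m[refl(r + dr, nr), refl(cc + dc, nc)]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

## Square polygon whose edges sit half a pixel outside the given 0-based
## pixel-center range, so it covers exactly those centers.
pixelSquare <- function(c0, c1, r0, r1) {
  cbind(
    c(c0 - 0.5, c1 + 0.5, c1 + 0.5, c0 - 0.5),
    c(r0 - 0.5, r0 - 0.5, r1 + 0.5, r1 + 0.5)
  )
}

## Readout table for concordance tests.
syntheticReadouts <- function(n = 63L, seed = 1L) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    genotype = NA_character_, condition = NA_character_,
    roi_area_um2 = runif(n, 4e5, 8e5),
    lesion_count = rpois(n, 800),
    lesion_density_per_mm2 = rlnorm(n, log(3000), 0.6),
    mean_lesion_size_um2 = rlnorm(n, log(0.9), 0.3),
    macro_count = rpois(n, 30),
    macro_fraction_pct = runif(n, 0.5, 3),
    macro_density_per_mm2 = rlnorm(n, log(50), 0.8),
    stringsAsFactors = FALSE
  )
}
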