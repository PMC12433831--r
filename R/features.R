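## Multiscale per-pixel features for bright-blob texture classification.
## All filtering is separable correlation with symmetric (reflect) padding.

#' @keywords internal
.reflectIndex <- function(idx, n) {
  ## symmetric reflection with edge repeat: ... 2 1 | 1 2 ... n | n n-1 ...
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0L, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m))
}

#' @keywords internal
.convRows <- function(m, k) {
  ## correlate each column with k along the row (vertical) direction
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(k)) {
    w <- k[o]
    if (w == 0) next
    idx <- .reflectIndex(seq_len(n) + (o - 1L - r), n)
    out <- out + w * m[idx, , drop = FALSE]
  }
  out
}

#' @keywords internal
.convCols <- function(m, k) t(.convRows(t(m), k))

#' @keywords internal
.sepConv <- function(m, kRow, kCol) .convCols(.convRows(m, kRow), kCol)

#' Discrete Gaussian and derivative kernels
#'
#' Sampled Gaussian kernels with moment corrections: the smoothing kernel
#' sums to one; the first-derivative kernel has zero sum and unit response to
#' a unit ramp; the second-derivative kernel has zero zeroth and first
#' moments and unit response to x^2/2. Radius is max(1, ceiling(3 sigma)).
#'
#' @param sigma positive smoothing scale in pixels.
#' @param order derivative order 0, 1 or 2.
#' @return numeric kernel vector of odd length.
#' @keywords internal
.gaussKernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    k <- x * g
    k / sum(x * k)  # correlation kernel: unit response to slope-1 ramp
  } else {
    k <- (x^2 - sigma^2) * g
    k <- k - mean(k)                 # zero DC
    k / sum(x^2 / 2 * k)             # unit response to x^2/2
  }
}

.BASE_FEATURES <- c(
  "gaussian", "gradmag", "log", "structure_max", "structure_min"
)

#' Compute the multiscale feature stack of an image
#'
#' For every pixel and every scale sigma, computes five base features:
#' Gaussian-smoothed intensity, Gaussian gradient magnitude, Laplacian of
#' Gaussian, and the maximum and minimum eigenvalues of the
#' Gaussian-smoothed structure tensor (integration scale equal to sigma).
#' This is a standard texture/blobness basis for detecting bright punctate
#' to patchy signal over textured background. Filters use symmetric
#' (reflect) border padding.
#'
#' @param image a [FluorescenceImage-class].
#' @param scalesPx strictly increasing positive smoothing scales in pixels
#'   (default \code{c(0.5, 1, 2, 4, 8)}).
#' @return A [FeatureStack-class] with \code{length(scalesPx) * 5} channels,
#'   ordered scale-major; channel names record the feature/scale manifest.
#' @examples
#' img <- FluorescenceImage(matrix(runif(64), 8, 8))
#' fs <- computeFeatureStack(img, scalesPx = c(1, 2))
#' dim(fs)
#' @export
computeFeatureStack <- function(image, scalesPx = c(0.5, 1, 2, 4, 8)) {
  stopifnot(is(image, "FluorescenceImage"))
  validObject(image)
  if (length(scalesPx) == 0L) stop("scalesPx must be non-empty")
  if (any(scalesPx <= 0)) stop("scalesPx must be positive")
  if (is.unsorted(scalesPx, strictly = TRUE)) {
    stop("scalesPx must be strictly increasing")
  }
  m <- image@pixels
  nf <- length(scalesPx) * length(.BASE_FEATURES)
  feats <- array(0, dim = c(nrow(m), ncol(m), nf))
  nms <- character(nf)
  i <- 0L
  for (s in scalesPx) {
    g0 <- .gaussKernel(s, 0L)
    g1 <- .gaussKernel(s, 1L)
    g2 <- .gaussKernel(s, 2L)
    sm <- .sepConv(m, g0, g0)
    ## x = column direction, y = row direction
    ix <- .sepConv(m, g0, g1)
    iy <- .sepConv(m, g1, g0)
    ixx <- .sepConv(m, g0, g2)
    iyy <- .sepConv(m, g2, g0)
    ## structure tensor smoothed at the same scale
    jxx <- .sepConv(ix * ix, g0, g0)
    jxy <- .sepConv(ix * iy, g0, g0)
    jyy <- .sepConv(iy * iy, g0, g0)
    tr2 <- (jxx + jyy) / 2
    disc <- sqrt(pmax(((jxx - jyy) / 2)^2 + jxy^2, 0))
    vals <- list(
      sm,
      sqrt(ix^2 + iy^2),
      ixx + iyy,
      tr2 + disc,
      tr2 - disc
    )
    for (b in seq_along(.BASE_FEATURES)) {
      i <- i + 1L
      feats[, , i] <- vals[[b]]
      nms[i] <- sprintf("%s_s%g", .BASE_FEATURES[b], s)
    }
  }
  new("FeatureStack",
    features = feats, scalesPx = as.numeric(scalesPx), featureNames = nms
  )
}
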