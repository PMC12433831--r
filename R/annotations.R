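## Even-odd polygon rasterization in the 0-based pixel-center frame.

#' Points-in-polygon test (even-odd rule)
#'
#' Vectorized crossing-number test. A point exactly on a horizontal edge
#' follows the usual half-open convention (edges are counted on
#' \code{[ymin, ymax)}), so adjacent polygons sharing an edge never claim a
#' pixel twice.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 matrix of polygon vertices (x, y), implicitly closed.
#' @return logical vector.
#' @keywords internal
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    y1 <- ys[i]; y2 <- ye[i]
    if (y1 == y2) next
    x1 <- xs[i]; x2 <- xe[i]
    crosses <- (y1 <= py & py < y2) | (y2 <= py & py < y1)
    if (any(crosses)) {
      xInt <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- px[crosses] < xInt
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' @keywords internal
.polygonInBounds <- function(poly, nr, nc) {
  all(poly[, 1] >= -0.5 & poly[, 1] <= nc - 0.5 &
      poly[, 2] >= -0.5 & poly[, 2] <= nr - 0.5)
}

#' Rasterize one polygon to a logical mask
#'
#' A pixel belongs to the polygon iff its center (0-based integer
#' coordinates) lies inside under the even-odd rule.
#'
#' @param poly n x 2 (x, y) vertex matrix.
#' @param nr,nc raster dimensions.
#' @return logical matrix (nr x nc).
#' @keywords internal
.rasterizePolygon <- function(poly, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  cmin <- max(1L, floor(min(poly[, 1])) + 1L)
  cmax <- min(nc, ceiling(max(poly[, 1])) + 1L)
  rmin <- max(1L, floor(min(poly[, 2])) + 1L)
  rmax <- min(nr, ceiling(max(poly[, 2])) + 1L)
  if (cmin > cmax || rmin > rmax) return(mask)
  rows <- rmin:rmax
  cols <- cmin:cmax
  grid <- expand.grid(r = rows, c = cols)
  inside <- .pointsInPolygon(grid$c - 1, grid$r - 1, poly)
  mask[cbind(grid$r[inside], grid$c[inside])] <- TRUE
  mask
}

#' Label raster codes
#'
#' Integer codes used by [rasterizeAnnotations()]: 0 = unlabeled,
#' 1 = lesion, 2 = ignore.
#' @format Named integer vector.
#' @export
LABEL_CODES <- c(UNLABELED = 0L, LESION = 1L, IGNORE = 2L)

#' Rasterize sparse training annotations
#'
#' Burns the two annotation classes into an integer label raster
#' (see [LABEL_CODES]). A pixel is labeled iff its center lies inside a
#' polygon (even-odd rule). Pixels claimed by polygons of both classes are
#' ambiguous supervision and raise an error. Following the training-set
#' guideline of the reference workflow (at least 100 annotated objects per
#' class, in equal numbers), smaller or unbalanced sets trigger a warning
#' but still rasterize.
#'
#' @param annots an [AnnotationSet-class].
#' @param image the [FluorescenceImage-class] the annotations refer to.
#' @return integer matrix with values in \code{LABEL_CODES}.
#' @export
rasterizeAnnotations <- function(annots, image) {
  stopifnot(is(annots, "AnnotationSet"), is(image, "FluorescenceImage"))
  validObject(annots)
  d <- dim(image@pixels)
  nr <- d[1]; nc <- d[2]
  lesion <- matrix(FALSE, nr, nc)
  ignore <- matrix(FALSE, nr, nc)
  for (p in annots@polygons) {
    if (!.polygonInBounds(p$coords, nr, nc)) {
      stop("annotation polygon falls outside the image bounds")
    }
    m <- .rasterizePolygon(p$coords, nr, nc)
    if (p$class == "lesion") lesion <- lesion | m else ignore <- ignore | m
  }
  if (any(lesion & ignore)) {
    stop("polygons of different classes overlap: ambiguous supervision")
  }
  ct <- annotationCounts(annots)
  if (any(ct < 100L)) {
    warning(sprintf(
      paste0("training-set guideline: at least 100 annotated objects per ",
             "class are recommended (got %d lesion, %d ignore)"),
      ct["lesion"], ct["ignore"]
    ))
  }
  if (ct["lesion"] != ct["ignore"]) {
    warning(sprintf(
      "unequal annotation counts between classes (%d lesion vs %d ignore); equal numbers are recommended",
      ct["lesion"], ct["ignore"]
    ))
  }
  labels <- matrix(LABEL_CODES[["UNLABELED"]], nr, nc)
  labels[ignore] <- LABEL_CODES[["IGNORE"]]
  labels[lesion] <- LABEL_CODES[["LESION"]]
  labels
}

#' Build the ROI mask and calibrated area
#'
#' The analysed region is the union of the include polygons minus the union
#' of the exclusion (artefact) polygons, rasterized at pixel centers with
#' the even-odd rule. Area is the number of included pixels times the
#' squared pixel size.
#'
#' @param roi a [RegionOfInterest-class].
#' @param image the [FluorescenceImage-class] being analysed.
#' @return list with \code{mask} (logical matrix) and \code{areaUm2}.
#' @examples
#' img <- FluorescenceImage(matrix(0, 120, 120), pixelSizeUm = 0.13)
#' sq <- cbind(c(-0.5, 99.5, 99.5, -0.5), c(-0.5, -0.5, 99.5, 99.5))
#' buildRoiMask(RegionOfInterest(sq), img)$areaUm2  # 10000 px * 0.0169
#' @export
buildRoiMask <- function(roi, image) {
  stopifnot(is(roi, "RegionOfInterest"), is(image, "FluorescenceImage"))
  validObject(roi)
  d <- dim(image@pixels)
  nr <- d[1]; nc <- d[2]
  mask <- matrix(FALSE, nr, nc)
  for (p in roi@includePolygons) {
    if (!.polygonInBounds(p, nr, nc)) {
      stop("include polygon falls outside the image bounds")
    }
    mask <- mask | .rasterizePolygon(p, nr, nc)
  }
  for (p in roi@excludePolygons) {
    if (!.polygonInBounds(p, nr, nc)) {
      stop("exclude polygon falls outside the image bounds")
    }
    mask <- mask & !.rasterizePolygon(p, nr, nc)
  }
  if (!any(mask)) stop("ROI mask is empty after applying exclusions")
  list(mask = mask, areaUm2 = sum(mask) * image@pixelSizeUm^2)
}

## ---- GeoJSON interchange ----------------------------------------------

#' Read polygon annotations from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features whose
#' \code{classification} property is \code{"lesion"}/\code{"ignore"}
#' (annotations) or \code{"roi"}/\code{"exclude"} (regions of interest).
#' Only exterior rings are used for annotation classes; ROI holes should be
#' supplied as separate \code{"exclude"} features.
#'
#' @param path GeoJSON file path.
#' @return An [AnnotationSet-class] or [RegionOfInterest-class], depending
#'   on the classes present.
#' @export
readAnnotationGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  for (f in gj$features) {
    cls <- f$properties$classification
    if (is.null(cls)) stop("feature without 'classification' property")
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stop("only Polygon features are supported")
    }
    ring <- geom$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    ## drop the closing vertex if the ring repeats it
    if (nrow(coords) > 3L && all(coords[1, ] == coords[nrow(coords), ])) {
      coords <- coords[-nrow(coords), , drop = FALSE]
    }
    polys[[length(polys) + 1L]] <- list(coords = coords, class = cls)
  }
  classes <- vapply(polys, function(p) p$class, character(1))
  if (all(classes %in% c("lesion", "ignore"))) {
    AnnotationSet(polys)
  } else if (all(classes %in% c("roi", "exclude"))) {
    RegionOfInterest(
      includePolygons = lapply(polys[classes == "roi"], `[[`, "coords"),
      excludePolygons = lapply(polys[classes == "exclude"], `[[`, "coords")
    )
  } else {
    stop(
      "mixed or unknown classification values: ",
      paste(unique(classes), collapse = ", ")
    )
  }
}

#' Write annotations or an ROI to GeoJSON
#'
#' Inverse of [readAnnotationGeoJSON()]; rings are closed on output.
#'
#' @param x an [AnnotationSet-class] or [RegionOfInterest-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGeoJSON <- function(x, path) {
  if (is(x, "AnnotationSet")) {
    polys <- x@polygons
  } else if (is(x, "RegionOfInterest")) {
    polys <- c(
      lapply(x@includePolygons, function(m) list(coords = m, class = "roi")),
      lapply(x@excludePolygons, function(m) list(coords = m, class = "exclude"))
    )
  } else {
    stop("x must be an AnnotationSet or RegionOfInterest")
  }
  features <- lapply(polys, function(p) {
    ring <- rbind(p$coords, p$coords[1, ])
    list(
      type = "Feature",
      properties = list(classification = p$class),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          as.numeric(ring[i, ])
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
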