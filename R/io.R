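## TIFF and CSV interchange, pipeline configuration, orchestration.

#' @keywords internal
.metaPixelSizeUm <- function(raw) {
  ## pixel size from TIFF resolution tags (pixels per cm / inch), when the
  ## reader exposes them
  xres <- attr(raw, "x.resolution")
  unit <- attr(raw, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0 &&
      !is.null(unit) && unit %in% c("cm", "inch")) {
    perUm <- if (unit == "cm") xres / 1e4 else xres / 25400
    1 / perUm
  } else {
    NULL
  }
}

#' @keywords internal
.resolvePixelSize <- function(metaPs, configPs, path = "<image>") {
  if (is.null(configPs)) {
    if (is.null(metaPs)) {
      stop("pixel size not in metadata and not supplied in configuration: ",
           path)
    }
    metaPs
  } else {
    if (!is.null(metaPs) && abs(metaPs - configPs) > 1e-9 * configPs) {
      warning(sprintf(
        "pixel size conflict for %s: metadata %.6g, configuration %.6g; configuration wins",
        path, metaPs, configPs
      ))
    }
    configPs
  }
}

#' Read a single-channel TIFF as a FluorescenceImage
#'
#' Intensities are read losslessly (\code{as.is}). The pixel size is taken
#' from the TIFF resolution metadata when present; a \code{pixelSizeUm}
#' supplied in the configuration overrides metadata (with a warning when
#' the two disagree). Multi-channel files require an explicit
#' \code{channel}.
#'
#' @param path TIFF file path.
#' @param pixelSizeUm optional pixel size override in micrometres.
#' @param channel channel index for multi-channel files.
#' @param sampleId sample identifier (default: file name without
#'   extension).
#' @return A [FluorescenceImage-class].
#' @export
readFluorescenceImage <- function(path, pixelSizeUm = NULL, channel = NULL,
                                  sampleId = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(raw)) == 3L) {
    if (is.null(channel)) {
      stop("multi-channel image without a channel selector: ", path)
    }
    raw <- raw[, , channel]
  }
  metaPs <- .metaPixelSizeUm(raw)
  ps <- .resolvePixelSize(metaPs, pixelSizeUm, path)
  if (is.null(sampleId)) {
    sampleId <- tools::file_path_sans_ext(basename(path))
  }
  m <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
  FluorescenceImage(m, pixelSizeUm = ps, sampleId = sampleId)
}

#' Write a FluorescenceImage to 16-bit TIFF
#'
#' Values must lie in [0, 65535]; they are stored as 16-bit unsigned
#' integers (rounded) with the pixel size recorded in the resolution tags
#' (pixels per cm).
#'
#' @param image a [FluorescenceImage-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFluorescenceImage <- function(image, path) {
  stopifnot(is(image, "FluorescenceImage"))
  m <- image@pixels
  if (max(m) > 65535) stop("intensities exceed the 16-bit range")
  tiff::writeTIFF(
    m / 65535, path,
    bits.per.sample = 16L,
    compression = "none",
    reduce = TRUE
  )
  invisible(path)
}

.READOUT_COLUMNS <- c(
  "sample_id", "genotype", "condition",
  "roi_area_um2", "lesion_count", "lesion_density_per_mm2",
  "mean_lesion_size_um2", "macro_count", "macro_fraction_pct",
  "macro_density_per_mm2"
)

#' Write per-sample readouts to CSV
#'
#' UTF-8 comma-separated file with a mandatory header, '.' decimal marks
#' and missing values as empty fields. Columns follow the readout table
#' schema: identifiers, then ROI area, lesion count, lesion density, mean
#' lesion size, macrolesion count, macrolesion fraction and macrolesion
#' density.
#'
#' @param readouts readout data.frame ([quantifySample()] schema).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeReadouts <- function(readouts, path) {
  missing <- setdiff(.READOUT_COLUMNS, names(readouts))
  if (length(missing) > 0L) {
    stop("readouts lack columns: ", paste(missing, collapse = ", "))
  }
  write.csv(readouts[, .READOUT_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a readout CSV written by [writeReadouts()]
#'
#' Validates the schema and the group labels; malformed rows are reported
#' with their line numbers. Empty fields become \code{NA}.
#'
#' @param path CSV path.
#' @return readout data.frame.
#' @export
readReadouts <- function(path) {
  if (!file.exists(path)) stop("no such readout file: ", path)
  nFields <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nFields != nFields[1])
  if (length(bad) > 0L) {
    stop(
      "malformed CSV ", path, ": inconsistent field count at line(s) ",
      paste(bad, collapse = ", ")
    )
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.READOUT_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("readout CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  badG <- which(!(is.na(df$genotype) | df$genotype %in% c("WT", "HET", "HOM")))
  if (length(badG) > 0L) {
    stop(
      "unknown genotype label at line(s) ",
      paste(badG + 1L, collapse = ", "), " of ", path
    )
  }
  badC <- which(!(is.na(df$condition) | df$condition %in% c("no_run", "run")))
  if (length(badC) > 0L) {
    stop(
      "unknown condition label at line(s) ",
      paste(badC + 1L, collapse = ", "), " of ", path
    )
  }
  numCols <- setdiff(.READOUT_COLUMNS, c("sample_id", "genotype", "condition"))
  for (cc in numCols) df[[cc]] <- as.numeric(df[[cc]])
  df[, .READOUT_COLUMNS]
}

## ---- configuration -----------------------------------------------------

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [runPipeline()]:
#' calibration, feature scales, classifier hyperparameters and seed,
#' lesion-extraction settings, the statistics alpha, and input/output
#' paths. Values mirror the reference workflow settings (0.13 um/px, five
#' scales, MLP classifier, min detection 0.01 um^2, macro threshold
#' 10 um^2, alpha 0.05).
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    pixel_size_um = 0.13,
    scales_px = c(0.5, 1, 2, 4, 8),
    classifier = list(
      hidden_units = 32L, max_epochs = 200L, decay = 0,
      max_pixels_per_class = 10000L, seed = 1L
    ),
    quant = list(
      min_detection_um2 = 0.01, macro_threshold_um2 = 10, connectivity = 8L
    ),
    alpha = 0.05,
    paths = list(
      train_images = character(0), train_annotations = character(0),
      val_images = character(0), val_truth_masks = character(0),
      sample_images = character(0), sample_rois = character(0),
      sample_genotypes = character(0), sample_conditions = character(0),
      classifier = NULL, out_dir = "xirplesion_out"
    )
  )
}

#' @keywords internal
.validateConfig <- function(cfg) {
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0) {
    stop("config: pixel_size_um must be positive")
  }
  if (length(cfg$scales_px) == 0L || any(cfg$scales_px <= 0) ||
      is.unsorted(cfg$scales_px, strictly = TRUE)) {
    stop("config: scales_px must be strictly increasing and positive")
  }
  q <- cfg$quant
  QuantConfig(q$min_detection_um2, q$macro_threshold_um2, q$connectivity)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config: alpha must be in (0, 1)")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML; unknown keys are
#' rejected, missing keys fall back to [defaultPipelineConfig()] values,
#' and every numeric field is validated before any stage runs.
#'
#' @param path YAML file path.
#' @return [readPipelineConfig()]: validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  base <- defaultPipelineConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) {
    stop("config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, cfg)
  .validateConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param cfg configuration list.
#' @return [writePipelineConfig()]: \code{path}, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  .validateConfig(utils::modifyList(defaultPipelineConfig(), cfg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @keywords internal
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

## ---- pipeline ----------------------------------------------------------

#' @keywords internal
.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains the workflow over the files named in the configuration: train the
#' pixel classifier on the annotated training images (or load an existing
#' classifier), select the deployed iteration on the validation images,
#' classify and quantify every sample within its ROI, write the readout
#' CSV, and (when group labels are present for all samples) run the
#' six-group statistics. An audit file records the package version, seeds,
#' configuration hash, per-stage timings and counts. An output directory
#' holding results from a different configuration hash is refused unless
#' \code{overwrite = TRUE}. Any stage failure raises an error naming the
#' stage.
#'
#' @param config configuration list or path to a YAML file
#'   (see [defaultPipelineConfig()]).
#' @param overwrite allow overwriting outputs produced under a different
#'   configuration hash.
#' @param quiet suppress progress messages.
#' @return list with \code{readouts}, \code{classifier}, \code{stats}
#'   (NULL without group labels), \code{audit} and the output paths,
#'   invisibly.
#' @export
runPipeline <- function(config, overwrite = FALSE, quiet = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else {
    .validateConfig(utils::modifyList(defaultPipelineConfig(), config))
  }
  hash <- .configHash(cfg)
  paths <- cfg$paths
  outDir <- paths$out_dir
  auditPath <- file.path(outDir, "audit.json")
  if (dir.exists(outDir) && file.exists(auditPath)) {
    prev <- jsonlite::read_json(auditPath)
    if (!identical(prev$config_hash, hash) && !overwrite) {
      stop(sprintf(
        "[stage:setup] output directory %s holds results for config %s (current %s); not overwriting",
        outDir, prev$config_hash, hash
      ), call. = FALSE)
    }
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  audit <- list(
    package = "xirplesion",
    version = as.character(utils::packageVersion("xirplesion")),
    config_hash = hash,
    seed = cfg$classifier$seed,
    stages = list()
  )
  timeStage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- .stageError(name, expr)
    audit$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    res
  }
  qc <- QuantConfig(
    cfg$quant$min_detection_um2, cfg$quant$macro_threshold_um2,
    cfg$quant$connectivity
  )
  hp <- list(
    hiddenUnits = cfg$classifier$hidden_units,
    maxEpochs = cfg$classifier$max_epochs,
    decay = cfg$classifier$decay,
    maxPixelsPerClass = cfg$classifier$max_pixels_per_class
  )

  clf <- if (!is.null(paths$classifier) && file.exists(paths$classifier) &&
             length(paths$train_images) == 0L) {
    timeStage("load_classifier", loadClassifier(paths$classifier))
  } else if (length(paths$train_images) > 0L) {
    note("training classifier on %d image(s)", length(paths$train_images))
    timeStage("train", {
      if (length(paths$train_annotations) != length(paths$train_images)) {
        stop("need one annotation file per training image")
      }
      stacks <- list()
      labels <- list()
      for (i in seq_along(paths$train_images)) {
        img <- readFluorescenceImage(
          paths$train_images[i], pixelSizeUm = cfg$pixel_size_um
        )
        stacks[[i]] <- computeFeatureStack(img, cfg$scales_px)
        ann <- readAnnotationGeoJSON(paths$train_annotations[i])
        labels[[i]] <- suppressWarnings(rasterizeAnnotations(ann, img))
      }
      trainClassifier(stacks, labels, hp = hp, seed = cfg$classifier$seed)
    })
  } else {
    .stageError("train", stop("no classifier file and no training images"))
  }

  if (length(paths$val_images) > 0L) {
    note("selecting iteration on %d validation image(s)",
         length(paths$val_images))
    clf <- timeStage("select", {
      vs <- list()
      vt <- list()
      for (i in seq_along(paths$val_images)) {
        img <- readFluorescenceImage(
          paths$val_images[i], pixelSizeUm = cfg$pixel_size_um
        )
        vs[[i]] <- computeFeatureStack(img, cfg$scales_px)
        tr <- readFluorescenceImage(
          paths$val_truth_masks[i], pixelSizeUm = cfg$pixel_size_um
        )
        vt[[i]] <- pixels(tr) > 0
      }
      selectClassifier(clf, vs, vt)
    })
  }
  clfPath <- file.path(outDir, "classifier.json")
  saveClassifier(clf, clfPath)

  readouts <- NULL
  if (length(paths$sample_images) > 0L) {
    note("quantifying %d sample(s)", length(paths$sample_images))
    readouts <- timeStage("quantify", {
      if (length(paths$sample_rois) != length(paths$sample_images)) {
        stop("need one ROI file per sample image")
      }
      rows <- lapply(seq_along(paths$sample_images), function(i) {
        img <- readFluorescenceImage(
          paths$sample_images[i], pixelSizeUm = cfg$pixel_size_um
        )
        roi <- readAnnotationGeoJSON(paths$sample_rois[i])
        gt <- if (length(paths$sample_genotypes) > 0L) {
          paths$sample_genotypes[i]
        } else {
          NA_character_
        }
        cd <- if (length(paths$sample_conditions) > 0L) {
          paths$sample_conditions[i]
        } else {
          NA_character_
        }
        quantifyImage(img, clf, roi, qc, genotype = gt, condition = cd)$readout
      })
      do.call(rbind, rows)
    })
    audit$stages$quantify$n_samples <- nrow(readouts)
    writeReadouts(readouts, file.path(outDir, "readouts.csv"))
  }

  statsReport <- NULL
  if (!is.null(readouts) && !anyNA(readouts$genotype) &&
      !anyNA(readouts$condition) &&
      all(table(readouts$genotype, readouts$condition) >= 2L) &&
      length(unique(readouts$genotype)) == 3L) {
    note("running six-group statistics")
    statsReport <- timeStage("stats", runStudyAnalysis(readouts, cfg$alpha))
    write.csv(
      statsReport$table, file.path(outDir, "stats_report.csv"),
      row.names = FALSE, na = ""
    )
  }
  jsonlite::write_json(
    audit, auditPath, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    readouts = readouts, classifier = clf, stats = statsReport,
    audit = audit,
    paths = list(
      out_dir = outDir, classifier = clfPath,
      readouts = if (is.null(readouts)) NULL else file.path(outDir, "readouts.csv"),
      stats = if (is.null(statsReport)) NULL else file.path(outDir, "stats_report.csv"),
      audit = auditPath
    )
  ))
}
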