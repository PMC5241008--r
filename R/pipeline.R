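## Pipeline configuration and end-to-end orchestration:
## register -> fuse -> segment -> crop -> mesh -> compare.

#' Construct a PipelineConfig
#'
#' @param similarity `"nmi"` or `"mi"`.
#' @param bins joint-histogram bins per axis.
#' @param stage1Tol,stage2Tol Powell relative tolerances (coarse, fine).
#' @param stage1Stride coarse-stage fixed-grid stride.
#' @param maxCycles Powell cycle cap per stage.
#' @param scaleFrozen keep scale fixed at 1 (rigid).
#' @param thresholdLow,thresholdHigh osseous HU window.
#' @param cropBox a [CropBox-class] or NULL.
#' @param outputDir output directory.
#' @param logLevel `"info"` or `"debug"`.
#' @param seed integer seed for stochastic steps.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(similarity = "nmi", bins = 64L, stage1Tol = 1e-2,
                           stage2Tol = 1e-4, stage1Stride = 4L,
                           maxCycles = 50L, scaleFrozen = TRUE,
                           thresholdLow = 300, thresholdHigh = 1000,
                           cropBox = NULL, outputDir = ".",
                           logLevel = "info", seed = 1L) {
  new("PipelineConfig", similarity = similarity, bins = as.integer(bins),
      stage1Tol = stage1Tol, stage2Tol = stage2Tol,
      stage1Stride = as.integer(stage1Stride),
      maxCycles = as.integer(maxCycles), scaleFrozen = scaleFrozen,
      thresholdLow = thresholdLow, thresholdHigh = thresholdHigh,
      cropBox = cropBox, outputDir = outputDir, logLevel = logLevel,
      seed = as.integer(seed))
}

.configKeys <- list(
  registration = c("similarity", "bins", "stage1_tol", "stage2_tol",
                   "stage1_stride", "max_cycles", "scale_frozen"),
  segmentation = c("threshold_low", "threshold_high"),
  crop_box = c("center_mm", "extents_mm", "orientation_deg"),
  output = c("dir", "log_level"),
  seed = character())

#' Read or write a pipeline configuration file (YAML)
#'
#' The file round-trips losslessly; unknown keys are rejected with the
#' offending key named.
#'
#' @param path YAML file.
#' @return a [PipelineConfig-class] (reader); `path` invisibly (writer).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(.configKeys))
  if (length(bad)) stop("unknown config key: ", bad[1])
  for (sec in intersect(names(y), c("registration", "segmentation",
                                    "crop_box", "output"))) {
    badk <- setdiff(names(y[[sec]]), .configKeys[[sec]])
    if (length(badk))
      stop("unknown config key: ", sec, ".", badk[1])
  }
  reg <- y$registration
  seg <- y$segmentation
  out <- y$output
  box <- if (!is.null(y$crop_box))
    cropBox(center = unlist(y$crop_box$center_mm),
            extents = unlist(y$crop_box$extents_mm),
            orientation = unlist(y$crop_box$orientation_deg))
  pipelineConfig(
    similarity = reg$similarity %||% "nmi",
    bins = reg$bins %||% 64L,
    stage1Tol = reg$stage1_tol %||% 1e-2,
    stage2Tol = reg$stage2_tol %||% 1e-4,
    stage1Stride = reg$stage1_stride %||% 4L,
    maxCycles = reg$max_cycles %||% 50L,
    scaleFrozen = reg$scale_frozen %||% TRUE,
    thresholdLow = seg$threshold_low %||% 300,
    thresholdHigh = seg$threshold_high %||% 1000,
    cropBox = box,
    outputDir = out$dir %||% ".",
    logLevel = out$log_level %||% "info",
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  y <- list(
    registration = list(similarity = config@similarity,
                        bins = config@bins,
                        stage1_tol = config@stage1Tol,
                        stage2_tol = config@stage2Tol,
                        stage1_stride = config@stage1Stride,
                        max_cycles = config@maxCycles,
                        scale_frozen = config@scaleFrozen),
    segmentation = list(threshold_low = config@thresholdLow,
                        threshold_high = config@thresholdHigh),
    output = list(dir = config@outputDir, log_level = config@logLevel),
    seed = config@seed)
  if (!is.null(config@cropBox))
    y$crop_box <- list(center_mm = config@cropBox@center,
                       extents_mm = config@cropBox@extents,
                       orientation_deg = config@cropBox@orientation)
  yaml::write_yaml(y, path)
  invisible(path)
}

## split a bone mask into condyle and fossa: the two largest 6-connected
## components, the lower centroid (z) being the condylar head
.splitBoneMask <- function(bone) {
  lab <- .cppComponents(as.integer(bone@voxels), dim(bone@voxels))
  n <- max(lab)
  if (n < 2)
    stop("bone mask has fewer than two components; cannot separate condyle and fossa")
  sizes <- tabulate(lab, n)
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  cz <- vapply(top2, function(l) {
    idx <- which(array(lab, dim(bone@voxels)) == l, arr.ind = TRUE) - 1
    mean(indexToWorld(bone, idx)[, 3])
  }, 0)
  condyleLab <- top2[which.min(cz)]
  fossaLab <- top2[which.max(cz)]
  arr <- array(lab, dim(bone@voxels))
  list(condyle = labelMask(arr == condyleLab, bone, label = "condyle",
                           provenance = bone@provenance),
       fossa = labelMask(arr == fossaLab, bone, label = "fossa",
                         provenance = bone@provenance))
}

.plog <- function(con, stage, t0, detail = "") {
  line <- sprintf("[%s] stage=%s elapsed=%.2fs %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(proc.time()[3] - t0), detail)
  if (!is.null(con)) writeLines(line, con)
  line
}

#' Run the full fusion pipeline
#'
#' Registers the moving MR to the fixed CBCT, writes the fused volume,
#' threshold-segments the osseous structures, splits and optionally crops
#' them, extracts unsmoothed STL surface models, and (when reference masks
#' are supplied) writes a comparison report per structure.  All inputs are
#' validated before any output is created.
#'
#' @param config a [PipelineConfig-class].
#' @param fixedPath path to the CBCT volume.
#' @param movingPath path to the MR volume.
#' @param referenceMasks optional named list (or directory of
#'   `<structure>.nii.gz`) of masks to compare the pipeline segmentation
#'   against (e.g. a second session, or phantom ground truth).
#' @return list with `transform` ([RegistrationResult-class]), `masks`,
#'   `meshes`, `reports` (per-structure [ComparisonReport-class] or NULL),
#'   `outputs` (paths written), `converged`.
#' @export
runPipeline <- function(config, fixedPath, movingPath,
                        referenceMasks = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  t0 <- proc.time()[3]
  # ---- validate inputs before writing anything
  if (!file.exists(fixedPath))
    stop("fixed (CBCT) input not found: ", fixedPath)
  if (!file.exists(movingPath))
    stop("moving (MR) input not found: ", movingPath)
  fixed <- readVolume(fixedPath, modality = "CT")
  moving <- readVolume(movingPath, modality = "MR")
  refs <- NULL
  if (!is.null(referenceMasks)) {
    if (is.character(referenceMasks)) {
      files <- list.files(referenceMasks, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
      nm <- sub("\\.nii(\\.gz)?$", "", basename(files))
      keep <- nm %in% c("condyle", "fossa", "disc")
      refs <- stats::setNames(
        lapply(which(keep), function(i) readMask(files[i], label = nm[i])),
        nm[keep])
    } else refs <- referenceMasks
  }
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config@outputDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  cfgPath <- file.path(config@outputDir, "config.yaml")
  writePipelineConfig(config, cfgPath)
  writeLines(sprintf("tmjfuse %s; config md5 %s; seed %d",
                     as.character(utils::packageVersion("tmjfuse")),
                     unname(tools::md5sum(cfgPath)), config@seed), logCon)
  outputs <- c(log = logPath, config = cfgPath)
  md5 <- function(p) unname(tools::md5sum(p))
  .plog(logCon, "inputs", t0,
        sprintf("fixed=%s(%s) moving=%s(%s)", fixedPath, md5(fixedPath),
                movingPath, md5(movingPath)))

  # ---- register
  ts <- proc.time()[3]
  reg <- registerVolumes(fixed, moving, similarity = config@similarity,
                         bins = config@bins,
                         freeScale = !config@scaleFrozen,
                         stage1Stride = config@stage1Stride,
                         stage1Tol = config@stage1Tol,
                         stage2Tol = config@stage2Tol,
                         maxCycles = config@maxCycles)
  trPath <- file.path(config@outputDir, "transform.json")
  writeTransform(reg@transform, trPath)
  outputs["transform"] <- trPath
  .plog(logCon, "register", ts,
        sprintf("%s=%.6f converged=%s out=%s(%s)", reg@similarityKind,
                reg@finalSimilarity, reg@converged, trPath, md5(trPath)))

  # ---- fuse
  ts <- proc.time()[3]
  fused <- fuseVolumes(fixed, moving, reg@transform)
  fusedPath <- file.path(config@outputDir, "fused.nii.gz")
  writeVolume(fused, fusedPath)
  outputs["fused"] <- fusedPath
  .plog(logCon, "fuse", ts, sprintf("out=%s(%s)", fusedPath, md5(fusedPath)))

  # ---- segment + crop
  ts <- proc.time()[3]
  bone <- thresholdSegment(fixed, config@thresholdLow, config@thresholdHigh)
  if (!is.null(config@cropBox)) bone <- applyCrop(bone, config@cropBox)
  masks <- .splitBoneMask(bone)
  maskDir <- file.path(config@outputDir, "masks")
  dir.create(maskDir, showWarnings = FALSE)
  for (nm in names(masks)) {
    p <- file.path(maskDir, paste0(nm, ".nii.gz"))
    writeMask(masks[[nm]], p)
    outputs[paste0("mask_", nm)] <- p
  }
  .plog(logCon, "segment", ts,
        sprintf("threshold=[%g,%g] condyle=%d fossa=%d voxels",
                config@thresholdLow, config@thresholdHigh,
                sum(masks$condyle@voxels), sum(masks$fossa@voxels)))

  # ---- mesh
  ts <- proc.time()[3]
  meshes <- lapply(masks, maskToMesh)
  for (nm in names(meshes)) {
    p <- file.path(config@outputDir, paste0(nm, ".stl"))
    writeSTL(meshes[[nm]], p)
    outputs[paste0("stl_", nm)] <- p
  }
  .plog(logCon, "mesh", ts,
        paste(vapply(names(meshes), function(nm)
          sprintf("%s=%dtri", nm, nrow(meshes[[nm]]@triangles)), ""),
          collapse = " "))

  # ---- compare
  reports <- NULL
  if (!is.null(refs) && length(refs)) {
    ts <- proc.time()[3]
    reports <- list()
    rows <- list()
    for (nm in intersect(names(masks), names(refs))) {
      rep <- compareModels(masks[[nm]], refs[[nm]])
      reports[[nm]] <- rep
      rows[[nm]] <- data.frame(structure = nm, rmsd_mm = rep@rmsd,
                               md_mm = rep@md, dsi = rep@dsi,
                               volume_a = rep@volumeA,
                               volume_b = rep@volumeB,
                               overlap = rep@overlap)
    }
    tab <- do.call(rbind, rows)
    csvPath <- file.path(config@outputDir, "report.csv")
    write.csv(tab, csvPath, row.names = FALSE)
    jsonPath <- file.path(config@outputDir, "report.json")
    jsonlite::write_json(tab, jsonPath, dataframe = "rows", digits = NA)
    outputs["report_csv"] <- csvPath
    outputs["report_json"] <- jsonPath
    .plog(logCon, "compare", ts,
          sprintf("structures=%s out=%s(%s)",
                  paste(tab$structure, collapse = ","), csvPath,
                  md5(csvPath)))
  }
  .plog(logCon, "done", t0, "")
  list(transform = reg, masks = masks, meshes = meshes, reports = reports,
       outputs = outputs, converged = reg@converged)
}
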