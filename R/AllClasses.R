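## S4 classes for volumes, transforms, histograms, masks, meshes and reports.

.checkGeometry <- function(object) {
  msg <- character()
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  d <- object@direction
  if (!is.matrix(d) || any(dim(d) != c(3L, 3L)) || any(!is.finite(d))) {
    msg <- c(msg, "direction must be a finite 3x3 matrix")
  } else {
    if (max(abs(crossprod(d) - diag(3))) > 1e-6)
      msg <- c(msg, "direction must be orthonormal")
    if (abs(det(d) - 1) > 1e-6)
      msg <- c(msg, "direction must have determinant +1 (right-handed)")
  }
  msg
}

#' ImageVolume: a 3-D scalar grid with world geometry
#'
#' A scalar volume (CBCT or MR) on a regular grid.  Voxel indices are
#' 0-based with voxel centres at integer indices; world coordinates are in
#' mm, LPS-oriented, related to indices by
#' `world = origin + direction %*% (index * spacing)`.
#'
#' @slot voxels numeric 3-D array of intensities.
#' @slot spacing mm per axis (length 3, all positive).
#' @slot origin world position (mm) of voxel (0,0,0).
#' @slot direction orthonormal 3x3 matrix of axis cosines, determinant +1.
#' @slot modality `"CT"` or `"MR"`.
#' @slot intensityUnits `"HU"` or `"arbitrary"`.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", modality = "character",
                 intensityUnits = "character"),
  validity = function(object) {
    msg <- .checkGeometry(object)
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (any(is.infinite(object@voxels)) || any(is.nan(object@voxels)))
      msg <- c(msg, paste("voxel values must be finite",
                          "(NA allowed only as out-of-bounds sentinel)"))
    if (!object@modality %in% c("CT", "MR"))
      msg <- c(msg, "modality must be 'CT' or 'MR'")
    if (!object@intensityUnits %in% c("HU", "arbitrary"))
      msg <- c(msg, "intensityUnits must be 'HU' or 'arbitrary'")
    if (length(msg)) msg else TRUE
  })

#' SliceGeometry: thickness and gap of an anisotropic MR acquisition
#'
#' @slot sliceThickness slice thickness in mm (> 0).
#' @slot interSliceGap gap between adjacent slices in mm (>= 0).
#' @slot sliceAxis axis index (1--3) perpendicular to the slices.
#' @export
setClass("SliceGeometry",
  representation(sliceThickness = "numeric", interSliceGap = "numeric",
                 sliceAxis = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@sliceThickness <= 0) msg <- c(msg, "sliceThickness must be > 0")
    if (object@interSliceGap < 0) msg <- c(msg, "interSliceGap must be >= 0")
    if (!object@sliceAxis %in% 1:3) msg <- c(msg, "sliceAxis must be 1, 2 or 3")
    if (length(msg)) msg else TRUE
  })

#' SimilarityTransform: rotation + translation (+ isotropic scale)
#'
#' Rigid/similarity mapping of world coordinates,
#' `y = center + scale * R %*% (x - center) + translation`, where `R` is
#' built from pitch/roll/yaw Euler angles (degrees) applied intrinsically
#' about x, then y, then z.
#'
#' @slot rotation pitch, roll, yaw in degrees (length 3).
#' @slot translation translation in mm (length 3).
#' @slot scale isotropic scale factor (> 0).
#' @slot center rotation centre in world mm (length 3).
#' @export
setClass("SimilarityTransform",
  representation(rotation = "numeric", translation = "numeric",
                 scale = "numeric", center = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0), scale = 1,
            center = c(0, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (length(object@rotation) != 3L || any(!is.finite(object@rotation)))
      msg <- c(msg, "rotation must be three finite angles (degrees)")
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be three finite values (mm)")
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
      msg <- c(msg, "scale must be a single positive value")
    if (length(object@center) != 3L || any(!is.finite(object@center)))
      msg <- c(msg, "center must be three finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' JointHistogram: binned joint intensity distribution of two volumes
#'
#' @slot counts bins x bins integer matrix; rows index fixed-image bins.
#' @slot edgesFixed,edgesMoving bin boundaries (length bins + 1).
#' @slot nSamples number of in-bounds paired voxels counted.
#' @export
setClass("JointHistogram",
  representation(counts = "matrix", edgesFixed = "numeric",
                 edgesMoving = "numeric", nSamples = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be non-negative integers")
    if (abs(sum(object@counts) - object@nSamples) > 0.5)
      msg <- c(msg, "counts must sum to nSamples")
    if (length(object@edgesFixed) != nrow(object@counts) + 1L ||
        length(object@edgesMoving) != ncol(object@counts) + 1L)
      msg <- c(msg, "edges must have one more entry than bins")
    if (length(msg)) msg else TRUE
  })

#' RegistrationResult: estimated transform with optimisation diagnostics
#'
#' @slot transform the estimated [SimilarityTransform-class].
#' @slot finalSimilarity similarity at the optimum (bits for MI,
#'   dimensionless for NMI).
#' @slot similarityKind `"MI"` or `"NMI"`.
#' @slot nIterations Powell cycles used per stage.
#' @slot converged logical; `FALSE` when a stage hit its cycle limit or the
#'   similarity decreased across the stage boundary.
#' @slot trace data.frame with one row per objective evaluation
#'   (stage, parameters, similarity).
#' @export
setClass("RegistrationResult",
  representation(transform = "SimilarityTransform",
                 finalSimilarity = "numeric", similarityKind = "character",
                 nIterations = "integer", converged = "logical",
                 trace = "data.frame"))

#' LabelMask: a binary segmentation sharing geometry with a parent volume
#'
#' @slot voxels integer 3-D array of 0/1.
#' @slot spacing,origin,direction geometry, identical to the parent volume.
#' @slot label one of `"condyle"`, `"fossa"`, `"disc"`, `"bone"`.
#' @slot provenance `"threshold"`, `"manual"` or `"edited"`.
#' @export
setClass("LabelMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", label = "character",
                 provenance = "character"),
  validity = function(object) {
    msg <- .checkGeometry(object)
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (!all(object@voxels %in% c(0L, 1L)))
      msg <- c(msg, "mask values must be strictly 0 or 1")
    if (!object@label %in% c("condyle", "fossa", "disc", "bone"))
      msg <- c(msg, "label must be condyle, fossa, disc or bone")
    if (!object@provenance %in% c("threshold", "manual", "edited"))
      msg <- c(msg, "provenance must be threshold, manual or edited")
    if (length(msg)) msg else TRUE
  })

#' CropBox: an oriented box with persisted pitch/roll/yaw
#'
#' @slot center box centre, world mm.
#' @slot extents full edge lengths, mm (all > 0).
#' @slot orientation pitch, roll, yaw in degrees (intrinsic x-y-z).
#' @export
setClass("CropBox",
  representation(center = "numeric", extents = "numeric",
                 orientation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@extents) != 3L || any(object@extents <= 0))
      msg <- c(msg, "extents must be three positive lengths (mm)")
    if (length(object@center) != 3L || any(!is.finite(object@center)))
      msg <- c(msg, "center must be three finite values (mm)")
    if (length(object@orientation) != 3L ||
        any(!is.finite(object@orientation)))
      msg <- c(msg, "orientation must be three finite angles (degrees)")
    if (length(msg)) msg else TRUE
  })

#' SurfaceMesh: a triangle surface model in world mm
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot triangles m x 3 integer matrix of 1-based vertex indices, wound so
#'   triangle normals point outward.
#' @slot label structure label.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L)
      msg <- c(msg, "vertices must be an n x 3 matrix")
    if (ncol(object@triangles) != 3L)
      msg <- c(msg, "triangles must be an m x 3 matrix")
    if (nrow(object@triangles) > 0 &&
        (min(object@triangles) < 1 ||
         max(object@triangles) > nrow(object@vertices)))
      msg <- c(msg, "triangle indices out of range")
    if (length(msg)) msg else TRUE
  })

#' ComparisonReport: reproducibility metrics for one structure pair
#'
#' @slot rmsd root-mean-square of pooled symmetric surface distances, mm.
#' @slot md maximum of the pooled surface distances, mm.
#' @slot dsi Dice similarity index in `[0, 1]`.
#' @slot volumeA,volumeB,overlap voxel counts of the two masks and their
#'   intersection on the reference grid.
#' @slot label structure label.
#' @slot directionPolicy how distances were pooled (`"symmetric"` or
#'   `"a_to_b"`).
#' @export
setClass("ComparisonReport",
  representation(rmsd = "numeric", md = "numeric", dsi = "numeric",
                 volumeA = "numeric", volumeB = "numeric",
                 overlap = "numeric", label = "character",
                 directionPolicy = "character"),
  validity = function(object) {
    msg <- character()
    if (object@dsi < 0 || object@dsi > 1)
      msg <- c(msg, "dsi must lie in [0, 1]")
    if (is.finite(object@rmsd) && is.finite(object@md) &&
        object@rmsd > object@md + 1e-12)
      msg <- c(msg, "rmsd cannot exceed md")
    if (length(msg)) msg else TRUE
  })

#' SummaryStats: mean and standard deviation of a metric column
#'
#' @slot mean arithmetic mean (raw, unrounded).
#' @slot sd sample standard deviation (n - 1 denominator; 0 when n = 1).
#' @slot n number of values.
#' @slot precision decimals used for reporting.
#' @slot rounding `"half-up"` or `"truncate"`.
#' @slot meanRounded,sdRounded values rounded per `rounding`/`precision`.
#' @export
setClass("SummaryStats",
  representation(mean = "numeric", sd = "numeric", n = "integer",
                 precision = "integer", rounding = "character",
                 meanRounded = "numeric", sdRounded = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: parameters of the deterministic digital TMJ phantom
#'
#' Stylised joint geometry: an ellipsoidal condylar head, a hemispherical
#' glenoid fossa shell above it, and a biconcave articular disc filling the
#' joint space, plus a bright (MR) retrodiscal region.  Defaults emulate the
#' target acquisitions: 0.25 mm isotropic CBCT, 3 mm MR slices with 0.3 mm
#' inter-slice gaps.
#'
#' @slot condyleCenter,condyleRadii ellipsoid centre and semi-axes, mm.
#' @slot fossaCenter fossa shell centre, mm.
#' @slot fossaRadii inner and outer shell radii, mm.
#' @slot fossaCapHeight dome cap: shell kept where z >= center z + cap, mm.
#' @slot discRadius disc extent in the joint plane, mm.
#' @slot discThickness centre and edge thickness of the biconcave lens, mm.
#' @slot retroCenter,retroRadii retrodiscal (bright MR) ellipsoid, mm.
#' @slot ctIntensities named HU levels: background, condyle, fossa, disc.
#' @slot mrIntensities named arbitrary-unit levels: background, bone, disc,
#'   retrodiscal.
#' @slot textureAmp texture amplitude per modality (ct, mr).
#' @slot noiseSd additive Gaussian noise SD per modality (ct, mr).
#' @slot ctSpacing isotropic CBCT voxel size, mm.
#' @slot ctDim CBCT grid dimensions.
#' @slot mrInPlane MR in-plane spacing, mm.
#' @slot mrSlice the MR [SliceGeometry-class].
#' @slot mrDim MR grid dimensions (slices along the slice axis).
#' @slot truthTransform ground-truth fixed-to-moving [SimilarityTransform-class].
#' @slot seed RNG seed controlling the noise draw.
#' @export
setClass("PhantomSpec",
  representation(condyleCenter = "numeric", condyleRadii = "numeric",
                 fossaCenter = "numeric", fossaRadii = "numeric",
                 fossaCapHeight = "numeric", discRadius = "numeric",
                 discThickness = "numeric", retroCenter = "numeric",
                 retroRadii = "numeric", ctIntensities = "numeric",
                 mrIntensities = "numeric", textureAmp = "numeric",
                 noiseSd = "numeric",
                 ctSpacing = "numeric", ctDim = "integer",
                 mrInPlane = "numeric", mrSlice = "SliceGeometry",
                 mrDim = "integer", truthTransform = "SimilarityTransform",
                 seed = "integer"))

#' PipelineConfig: settings for the end-to-end fusion pipeline
#'
#' @slot similarity `"nmi"` or `"mi"`.
#' @slot bins joint-histogram bins per axis.
#' @slot stage1Tol,stage2Tol relative improvement tolerances of the coarse
#'   and fine Powell stages.
#' @slot stage1Stride fixed-grid sampling stride of the coarse stage.
#' @slot maxCycles Powell cycle cap per stage.
#' @slot scaleFrozen keep isotropic scale fixed at 1.
#' @slot thresholdLow,thresholdHigh osseous HU window.
#' @slot cropBox the persisted [CropBox-class] (or NULL).
#' @slot outputDir where pipeline outputs are written.
#' @slot logLevel `"info"` or `"debug"`.
#' @slot seed integer seed forwarded to any stochastic step.
#' @export
setClass("PipelineConfig",
  representation(similarity = "character", bins = "integer",
                 stage1Tol = "numeric", stage2Tol = "numeric",
                 stage1Stride = "integer", maxCycles = "integer",
                 scaleFrozen = "logical", thresholdLow = "numeric",
                 thresholdHigh = "numeric", cropBox = "ANY",
                 outputDir = "character", logLevel = "character",
                 seed = "integer"),
  prototype(similarity = "nmi", bins = 64L, stage1Tol = 1e-2,
            stage2Tol = 1e-4, stage1Stride = 4L, maxCycles = 50L,
            scaleFrozen = TRUE, thresholdLow = 300, thresholdHigh = 1000,
            cropBox = NULL, outputDir = ".", logLevel = "info", seed = 1L),
  validity = function(object) {
    msg <- character()
    if (!object@similarity %in% c("nmi", "mi"))
      msg <- c(msg, "similarity must be 'nmi' or 'mi'")
    if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
    if (object@thresholdLow >= object@thresholdHigh)
      msg <- c(msg, "thresholdLow must be below thresholdHigh")
    if (!is.null(object@cropBox) && !is(object@cropBox, "CropBox"))
      msg <- c(msg, "cropBox must be a CropBox or NULL")
    if (length(msg)) msg else TRUE
  })
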