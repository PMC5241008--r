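## Generics and accessors.

#' @describeIn ImageVolume-class voxel array accessor
#' @param x an object with voxel data.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @describeIn ImageVolume-class voxel spacing (mm) accessor
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @describeIn ImageVolume-class world origin (mm) accessor
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @describeIn ImageVolume-class direction cosine matrix accessor
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @describeIn ImageVolume-class modality accessor
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @describeIn LabelMask-class structure label accessor
#' @param x an object carrying a structure label.
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))

#' @describeIn LabelMask-class provenance accessor
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn SurfaceMesh-class vertex matrix accessor
#' @param x a mesh.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @describeIn SurfaceMesh-class triangle index matrix accessor
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

setMethod("voxels", "ImageVolume", function(x) x@voxels)
setMethod("spacing", "ImageVolume", function(x) x@spacing)
setMethod("origin", "ImageVolume", function(x) x@origin)
setMethod("direction", "ImageVolume", function(x) x@direction)
setMethod("modality", "ImageVolume", function(x) x@modality)

setMethod("voxels", "LabelMask", function(x) x@voxels)
setMethod("spacing", "LabelMask", function(x) x@spacing)
setMethod("origin", "LabelMask", function(x) x@origin)
setMethod("direction", "LabelMask", function(x) x@direction)
setMethod("structureLabel", "LabelMask", function(x) x@label)
setMethod("provenance", "LabelMask", function(x) x@provenance)

setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)
setMethod("structureLabel", "SurfaceMesh", function(x) x@label)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume (%s, %s): %d x %d x %d voxels\n",
              object@modality, object@intensityUnits, d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n",
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  origin  (mm): %s\n",
              paste(format(object@origin), collapse = ", ")))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(object@voxels), max(object@voxels)))
  invisible(object)
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelMask '%s' (%s): %d x %d x %d voxels, %d set\n",
              object@label, object@provenance, d[1], d[2], d[3],
              sum(object@voxels)))
  invisible(object)
})

setMethod("show", "SimilarityTransform", function(object) {
  cat("SimilarityTransform (intrinsic x-y-z Euler, LPS mm)\n")
  cat(sprintf("  rotation (deg):    %s\n",
              paste(format(object@rotation), collapse = ", ")))
  cat(sprintf("  translation (mm):  %s\n",
              paste(format(object@translation), collapse = ", ")))
  cat(sprintf("  scale: %g   center (mm): %s\n", object@scale,
              paste(format(object@center), collapse = ", ")))
  invisible(object)
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh '%s': %d vertices, %d triangles\n",
              object@label, nrow(object@vertices), nrow(object@triangles)))
  invisible(object)
})

setMethod("show", "JointHistogram", function(object) {
  cat(sprintf("JointHistogram: %d x %d bins, %g samples\n",
              nrow(object@counts), ncol(object@counts), object@nSamples))
  invisible(object)
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%s = %.6f, %s)\n", object@similarityKind,
              object@finalSimilarity,
              if (object@converged) "converged" else "NOT converged"))
  show(object@transform)
  cat(sprintf("  Powell cycles per stage: %s; %d objective evaluations\n",
              paste(object@nIterations, collapse = ", "),
              nrow(object@trace)))
  invisible(object)
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf(
    "ComparisonReport '%s' (%s distances)\n  RMSD %.4f mm, MD %.4f mm, DSI %.4f\n",
    object@label, object@directionPolicy, object@rmsd, object@md,
    object@dsi))
  cat(sprintf("  volumes (voxels): A %d, B %d, overlap %d\n",
              object@volumeA, object@volumeB, object@overlap))
  invisible(object)
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: n = %d, mean %s (%s), sd %s (raw %.6g)\n",
              object@n, format(object@meanRounded), object@rounding,
              format(object@sdRounded), object@sd))
  invisible(object)
})
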