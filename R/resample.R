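## Resampling onto a reference grid and inter-slice gap filling.

#' Fill inter-slice gaps of an anisotropic MR acquisition
#'
#' Rebuilds the volume on a uniform fine grid along the slice axis; every
#' output slice is the exact copy of the acquired slice whose centre is
#' nearest (replication, no interpolation across the gap; ties resolve to
#' the lower slice index).  The output grid spans the acquired slice
#' centres.  In-plane axes are untouched.
#'
#' @param vol an [ImageVolume-class] whose spacing along `geom@sliceAxis`
#'   equals `sliceThickness + interSliceGap`.
#' @param geom a [SliceGeometry-class].
#' @param targetSpacing output spacing along the slice axis, mm; must not
#'   exceed the slice thickness.  Default 0.25 (the CBCT reference grid).
#' @return an [ImageVolume-class] with uniform fine spacing along the slice
#'   axis.
#' @examples
#' v <- imageVolume(array(rep(1:8, each = 16), c(4, 4, 8)),
#'                  spacing = c(1, 1, 3.3), modality = "MR")
#' g <- sliceGeometry(3, 0.3, sliceAxis = 3)
#' dim(voxels(fillSliceGaps(v, g)))
#' @export
fillSliceGaps <- function(vol, geom, targetSpacing = 0.25) {
  stopifnot(is(vol, "ImageVolume"), is(geom, "SliceGeometry"))
  ax <- geom@sliceAxis
  pitch <- geom@sliceThickness + geom@interSliceGap
  if (abs(vol@spacing[ax] - pitch) > 1e-6)
    stop(sprintf(
      "slice geometry inconsistent with volume: spacing[%d] = %g mm but thickness + gap = %g mm",
      ax, vol@spacing[ax], pitch))
  if (targetSpacing > geom@sliceThickness + 1e-12)
    stop("targetSpacing must not exceed the slice thickness")
  nIn <- dim(vol@voxels)[ax]
  span <- (nIn - 1) * pitch
  nOut <- floor(span / targetSpacing + 1e-9) + 1L
  # nearest acquired slice centre for each output slice centre
  pos <- (seq_len(nOut) - 1) * targetSpacing
  lower <- pmin(pmax(floor(pos / pitch), 0), nIn - 1)
  pickLower <- (pos - lower * pitch) <= (pitch / 2 + 1e-12)  # tie -> lower
  src <- as.integer(ifelse(pickLower, lower, pmin(lower + 1, nIn - 1))) + 1L
  idx <- list(seq_len(dim(vol@voxels)[1]), seq_len(dim(vol@voxels)[2]),
              seq_len(dim(vol@voxels)[3]))
  idx[[ax]] <- src
  out <- vol@voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sp <- vol@spacing
  sp[ax] <- targetSpacing
  imageVolume(out, spacing = sp, origin = vol@origin,
              direction = vol@direction, modality = vol@modality,
              intensityUnits = vol@intensityUnits)
}

#' Resample a moving volume onto a reference grid
#'
#' Samples `moving` at the transform-mapped world position of every
#' reference voxel centre.  Positions outside the moving grid are marked
#' `NA` (they are excluded from joint histograms rather than zero-filled).
#'
#' @param moving,reference [ImageVolume-class] objects.
#' @param transform a [SimilarityTransform-class] mapping fixed/reference
#'   world coordinates into moving world coordinates (identity by default).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return an [ImageVolume-class] on the reference grid (geometry copied
#'   from `reference`, modality from `moving`); out-of-bounds voxels `NA`.
#' @export
resampleToGrid <- function(moving, reference,
                           transform = similarityTransform(),
                           interpolation = c("linear", "nearest")) {
  stopifnot(is(moving, "ImageVolume"), is(reference, "ImageVolume"))
  interpolation <- match.arg(interpolation)
  if (transform@scale < 1e-12) stop("degenerate transform: scale ~ 0")
  A <- indexToIndexAffine(reference, moving, transform)
  vals <- .cppResample(as.numeric(moving@voxels), dim(moving@voxels), A,
                       dim(reference@voxels),
                       if (interpolation == "linear") 0L else 1L)
  new("ImageVolume",
      voxels = array(vals, dim(reference@voxels)),
      spacing = reference@spacing, origin = reference@origin,
      direction = reference@direction, modality = moving@modality,
      intensityUnits = moving@intensityUnits)
}

## fuse a registered pair for visual output: CBCT grid with the MR resampled
## through the estimated transform; returns both layers on one grid
fuseVolumes <- function(fixed, moving, transform,
                        interpolation = "linear") {
  mr <- resampleToGrid(moving, fixed, transform, interpolation)
  vox <- mr@voxels
  vox[is.na(vox)] <- 0
  imageVolume(vox, spacing = fixed@spacing, origin = fixed@origin,
              direction = fixed@direction, modality = moving@modality,
              intensityUnits = moving@intensityUnits)
}
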