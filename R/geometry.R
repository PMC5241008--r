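## World/index geometry and similarity transforms.

#' Construct an ImageVolume
#'
#' @param voxels numeric 3-D array.
#' @param spacing voxel size in mm per axis.
#' @param origin world position (mm) of voxel (0,0,0).
#' @param direction orthonormal 3x3 direction cosine matrix.
#' @param modality `"CT"` or `"MR"`.
#' @param intensityUnits `"HU"` or `"arbitrary"`; defaults to `"HU"` for CT.
#' @return an [ImageVolume-class].
#' @examples
#' v <- imageVolume(array(0, c(4, 4, 4)), spacing = c(0.25, 0.25, 0.25))
#' spacing(v)
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3), modality = c("CT", "MR"),
                        intensityUnits = NULL) {
  modality <- match.arg(modality)
  if (is.null(intensityUnits))
    intensityUnits <- if (modality == "CT") "HU" else "arbitrary"
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction,
      modality = modality, intensityUnits = intensityUnits)
}

#' Construct a LabelMask on the grid of a parent volume
#'
#' @param voxels 3-D array of 0/1 (logical or numeric accepted).
#' @param geometry an [ImageVolume-class] or [LabelMask-class] supplying the
#'   grid geometry, or a list with `spacing`, `origin`, `direction`.
#' @param label structure name: `"condyle"`, `"fossa"`, `"disc"` or `"bone"`.
#' @param provenance `"threshold"`, `"manual"` or `"edited"`.
#' @return a [LabelMask-class].
#' @export
labelMask <- function(voxels, geometry, label = "bone",
                      provenance = "manual") {
  g <- asGeometry(geometry)
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  new("LabelMask", voxels = vox, spacing = g$spacing, origin = g$origin,
      direction = g$direction, label = label, provenance = provenance)
}

asGeometry <- function(x) {
  if (is(x, "ImageVolume") || is(x, "LabelMask"))
    list(spacing = x@spacing, origin = x@origin, direction = x@direction)
  else if (is.list(x) && all(c("spacing", "origin", "direction") %in% names(x)))
    x[c("spacing", "origin", "direction")]
  else stop("cannot interpret geometry from object of class ", class(x)[1])
}

sameGeometry <- function(a, b, tol = 1e-6) {
  ga <- asGeometry(a); gb <- asGeometry(b)
  all(dim(a@voxels) == dim(b@voxels)) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$direction - gb$direction)) < tol
}

#' Construct a SliceGeometry
#'
#' @param sliceThickness slice thickness, mm.
#' @param interSliceGap inter-slice gap, mm.
#' @param sliceAxis axis (1--3) perpendicular to the slices.
#' @return a [SliceGeometry-class].
#' @export
sliceGeometry <- function(sliceThickness = 3, interSliceGap = 0.3,
                          sliceAxis = 1L) {
  new("SliceGeometry", sliceThickness = sliceThickness,
      interSliceGap = interSliceGap, sliceAxis = as.integer(sliceAxis))
}

#' Construct a SimilarityTransform
#'
#' @param rotation pitch, roll, yaw in degrees (intrinsic x-y-z order).
#' @param translation translation in mm.
#' @param scale isotropic scale (default 1, i.e. rigid).
#' @param center rotation centre in world mm.
#' @return a [SimilarityTransform-class].
#' @examples
#' tr <- similarityTransform(rotation = c(3, -2, 5), translation = c(4, -3, 2))
#' applyTransform(tr, c(0, 0, 0))
#' @export
similarityTransform <- function(rotation = c(0, 0, 0),
                                translation = c(0, 0, 0), scale = 1,
                                center = c(0, 0, 0)) {
  new("SimilarityTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), scale = as.numeric(scale),
      center = as.numeric(center))
}

#' Euler angles to rotation matrix and back
#'
#' Angles are pitch/roll/yaw in degrees, applied intrinsically about x,
#' then y, then z: `R = Rx(pitch) %*% Ry(roll) %*% Rz(yaw)`.
#'
#' @param angles length-3 numeric, degrees.
#' @return `eulerToMatrix`: a 3x3 rotation matrix; `matrixToEuler`: the
#'   angles (degrees) recovering `R` (yaw set to 0 at gimbal lock).
#' @export
eulerToMatrix <- function(angles) {
  a <- angles * pi / 180
  cp <- cos(a[1]); sp <- sin(a[1])
  cr <- cos(a[2]); sr <- sin(a[2])
  cy <- cos(a[3]); sy <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cp, -sp), c(0, sp, cp))
  ry <- rbind(c(cr, 0, sr), c(0, 1, 0), c(-sr, 0, cr))
  rz <- rbind(c(cy, -sy, 0), c(sy, cy, 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

#' @rdname eulerToMatrix
#' @param R a 3x3 rotation matrix.
#' @export
matrixToEuler <- function(R) {
  roll <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(roll)) > 1e-9) {
    pitch <- atan2(-R[2, 3], R[3, 3])
    yaw <- atan2(-R[1, 2], R[1, 1])
  } else {  # gimbal lock: fold yaw into pitch
    pitch <- atan2(R[2, 1], R[2, 2])
    yaw <- 0
  }
  c(pitch, roll, yaw) * 180 / pi
}

#' Rotation matrix of a SimilarityTransform
#' @param transform a [SimilarityTransform-class].
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(transform) eulerToMatrix(transform@rotation)

#' Apply a similarity transform to world points
#'
#' @param transform a [SimilarityTransform-class].
#' @param points numeric vector of length 3 or an n x 3 matrix, world mm.
#' @return transformed points, same shape as the input.
#' @export
applyTransform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  R <- rotationMatrix(transform)
  ctr <- transform@center
  out <- sweep(sweep(p, 2, ctr) %*% t(R) * transform@scale, 2,
               ctr + transform@translation, `+`)
  if (vec) drop(out) else out
}

#' Invert a similarity transform
#'
#' `composeTransforms(invertTransform(t), t)` is the identity (same centre).
#' @param transform a [SimilarityTransform-class].
#' @return the inverse [SimilarityTransform-class].
#' @export
invertTransform <- function(transform) {
  R <- rotationMatrix(transform)
  s <- transform@scale
  similarityTransform(rotation = matrixToEuler(t(R)),
                      translation = as.numeric(-(1 / s) * t(R) %*%
                                               transform@translation),
                      scale = 1 / s, center = transform@center)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `second` after `first`,
#' i.e. `applyTransform(composeTransforms(second, first), x) ==
#' applyTransform(second, applyTransform(first, x))`.
#'
#' @param second,first the two [SimilarityTransform-class] objects.
#' @return the composed [SimilarityTransform-class] (centre taken from
#'   `first`).
#' @export
composeTransforms <- function(second, first) {
  R1 <- rotationMatrix(first); R2 <- rotationMatrix(second)
  s1 <- first@scale; s2 <- second@scale
  c1 <- first@center; c2 <- second@center
  t12 <- c2 - c1 + s2 * as.numeric(R2 %*% (c1 + first@translation - c2)) +
    second@translation
  similarityTransform(rotation = matrixToEuler(R2 %*% R1),
                      translation = t12, scale = s1 * s2, center = c1)
}

#' Map continuous voxel indices to world coordinates
#'
#' Voxel indices are 0-based with centres at integer indices;
#' `world = origin + direction %*% (index * spacing)`.  Extrapolation beyond
#' the grid is allowed.
#'
#' @param vol an [ImageVolume-class] or [LabelMask-class].
#' @param index length-3 vector or n x 3 matrix of continuous 0-based indices.
#' @return world coordinates (mm), same shape as `index`.
#' @examples
#' v <- imageVolume(array(0, c(8, 8, 8)), spacing = c(0.25, 0.25, 0.25))
#' indexToWorld(v, c(4, 0, 0))
#' @export
indexToWorld <- function(vol, index) {
  g <- asGeometry(vol)
  vec <- is.null(dim(index))
  i <- if (vec) matrix(index, 1, 3) else as.matrix(index)
  out <- sweep(sweep(i, 2, g$spacing, `*`) %*% t(g$direction), 2, g$origin,
               `+`)
  if (vec) drop(out) else out
}

#' @rdname indexToWorld
#' @param world world coordinates (mm), length-3 vector or n x 3 matrix.
#' @export
worldToIndex <- function(vol, world) {
  g <- asGeometry(vol)
  vec <- is.null(dim(world))
  w <- if (vec) matrix(world, 1, 3) else as.matrix(world)
  out <- sweep(sweep(w, 2, g$origin) %*% g$direction, 2, g$spacing, `/`)
  if (vec) drop(out) else out
}

## 3x4 affine mapping 0-based indices of grid `from` to 0-based indices of
## grid `to`, optionally through a world-space similarity transform.
indexToIndexAffine <- function(from, to, transform = NULL) {
  gf <- asGeometry(from); gt <- asGeometry(to)
  A <- gf$direction %*% diag(gf$spacing)       # index -> world (linear part)
  b <- gf$origin
  if (!is.null(transform)) {
    R <- rotationMatrix(transform) * transform@scale
    b <- transform@center + as.numeric(R %*% (b - transform@center)) +
      transform@translation
    A <- R %*% A
  }
  Minv <- diag(1 / gt$spacing) %*% t(gt$direction)  # world -> index
  cbind(Minv %*% A, as.numeric(Minv %*% (b - gt$origin)))
}

## world centre of a volume's field of view
volumeCenter <- function(vol) {
  indexToWorld(vol, (dim(vol@voxels) - 1) / 2)
}
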