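## Threshold-based osseous segmentation, mask editing, oriented crop box,
## and rasterisation of per-slice manual disc contours.

#' Threshold segmentation of osseous structures on CT
#'
#' Marks every voxel whose intensity lies in the closed interval
#' `[low, high]`.  The defaults 300--1000 HU delimit cortical/trabecular
#' bone on CBCT, but CBCT grey values are scanner-dependent, so both ends
#' are exposed.
#'
#' @param ct a CT [ImageVolume-class].
#' @param low,high HU window (closed on both ends).
#' @param label label for the resulting mask.
#' @return a [LabelMask-class] with provenance `"threshold"`.
#' @examples
#' ct <- imageVolume(array(c(0, 400, 1200), c(3, 1, 1)))
#' sum(voxels(thresholdSegment(ct)))
#' @export
thresholdSegment <- function(ct, low = 300, high = 1000, label = "bone") {
  stopifnot(is(ct, "ImageVolume"))
  if (ct@modality != "CT")
    stop("thresholdSegment expects a CT volume (got ", ct@modality, ")")
  if (low >= high) stop("low must be below high")
  labelMask(ct@voxels >= low & ct@voxels <= high, ct, label = label,
            provenance = "threshold")
}

#' Manual add/erase correction of a mask
#'
#' `result = (base U additions) \\ erasures`; a voxel present in both
#' additions and erasures ends up erased.
#'
#' @param base,additions,erasures [LabelMask-class] objects on one grid.
#' @return the edited [LabelMask-class] (provenance `"edited"`).
#' @export
editMask <- function(base, additions, erasures) {
  stopifnot(is(base, "LabelMask"), is(additions, "LabelMask"),
            is(erasures, "LabelMask"))
  if (!sameGeometry(base, additions) || !sameGeometry(base, erasures))
    stop("editMask requires identical geometry for base, additions and erasures")
  out <- (base@voxels | additions@voxels) & !erasures@voxels
  labelMask(out, base, label = base@label, provenance = "edited")
}

#' Construct a CropBox
#'
#' @param center box centre, world mm.
#' @param extents full edge lengths, mm; default a 25 mm cube (large enough
#'   to hold condyle, fossa and the posterior slope of the eminence).
#' @param orientation pitch/roll/yaw in degrees (intrinsic x-y-z).
#' @return a [CropBox-class].
#' @export
cropBox <- function(center = c(0, 0, 0), extents = c(25, 25, 25),
                    orientation = c(0, 0, 0)) {
  new("CropBox", center = as.numeric(center), extents = as.numeric(extents),
      orientation = as.numeric(orientation))
}

#' Crop a mask with an oriented box
#'
#' Voxels whose centres fall outside the oriented box are zeroed; inside
#' voxels are untouched.  The box parameters (centre, extents,
#' pitch/roll/yaw) can be serialised with [writeCropBox()] and reused in a
#' later session so the second segmentation is cropped identically.
#'
#' @param mask a [LabelMask-class].
#' @param box a [CropBox-class].
#' @return the cropped [LabelMask-class].
#' @export
applyCrop <- function(mask, box) {
  stopifnot(is(mask, "LabelMask"), is(box, "CropBox"))
  d <- dim(mask@voxels)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w <- indexToWorld(mask, idx)
  R <- eulerToMatrix(box@orientation)
  local <- sweep(w, 2, box@center) %*% R   # world -> box frame (R^T op)
  inside <- abs(local[, 1]) <= box@extents[1] / 2 &
    abs(local[, 2]) <= box@extents[2] / 2 &
    abs(local[, 3]) <= box@extents[3] / 2
  out <- mask@voxels & array(inside, d)
  if (!any(out))
    warning("crop box does not intersect any set voxel; mask is empty")
  labelMask(out, mask, label = mask@label, provenance = mask@provenance)
}

#' Serialise a crop box to JSON (bit-exact round trip)
#' @param box a [CropBox-class].
#' @param path JSON path.
#' @return `path` invisibly; `readCropBox` returns the box.
#' @export
writeCropBox <- function(box, path) {
  jsonlite::write_json(list(center_mm = box@center,
                            extents_mm = box@extents,
                            orientation_deg = box@orientation),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCropBox
#' @export
readCropBox <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cropBox(center = obj$center_mm, extents = obj$extents_mm,
          orientation = obj$orientation_deg)
}

## do two 2-D segments properly intersect?
.segIntersect <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.polygonSelfIntersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next        # adjacent around the loop
      if (.segIntersect(pts[i, ], pts[i %% n + 1, ],
                        pts[j, ], pts[j %% n + 1, ])) return(TRUE)
    }
  }
  FALSE
}

## even-odd point-in-polygon, vectorised over points
.pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterise per-slice manual contours into a mask
#'
#' Each contour is a closed polygon (first point may equal the last, or
#' closure is implicit) drawn on one slice of the reference grid, with
#' vertices in the in-plane world coordinates of that slice.  A voxel is
#' set exactly when its centre lies inside its slice's polygon under the
#' even-odd rule.  Slices without contours stay empty.
#'
#' @param contours list of contours; each is
#'   `list(sliceIndex = <0-based slice index>, points = <n x 2 world-mm
#'   matrix>)`.  Multiple contours on one slice combine by even-odd parity.
#' @param reference an [ImageVolume-class] (or [LabelMask-class]) supplying
#'   the grid.
#' @param sliceAxis axis (1--3) the contours are drawn perpendicular to;
#'   default 1 (sagittal MR sections).
#' @param label structure label (default `"disc"`).
#' @return a [LabelMask-class] with provenance `"manual"`.
#' @export
contoursToMask <- function(contours, reference, sliceAxis = 1L,
                           label = "disc") {
  g <- asGeometry(reference)
  d <- dim(voxels(reference))
  inPlane <- setdiff(1:3, sliceAxis)
  out <- array(FALSE, d)
  idxPlane <- as.matrix(expand.grid(a = seq_len(d[inPlane[1]]) - 1,
                                    b = seq_len(d[inPlane[2]]) - 1))
  for (ct in contours) {
    k <- ct$sliceIndex
    if (k < 0 || k > d[sliceAxis] - 1)
      stop("contour sliceIndex out of range: ", k)
    pts <- as.matrix(ct$points)
    if (nrow(pts) >= 2 &&
        all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12))
      pts <- pts[-nrow(pts), , drop = FALSE]
    if (nrow(pts) < 3 || nrow(unique(pts)) < 3)
      stop("contour on slice ", k, " needs at least 3 distinct vertices")
    if (.polygonSelfIntersects(pts))
      stop("self-intersecting contour rejected on slice ", k)
    idx <- matrix(0, nrow(idxPlane), 3)
    idx[, inPlane[1]] <- idxPlane[, 1]
    idx[, inPlane[2]] <- idxPlane[, 2]
    idx[, sliceAxis] <- k
    w <- indexToWorld(list(spacing = g$spacing, origin = g$origin,
                           direction = g$direction), idx)
    inside <- .pointInPolygon(w[, inPlane[1]], w[, inPlane[2]], pts)
    plane <- array(FALSE, d)
    flat <- matrix(FALSE, d[inPlane[1]], d[inPlane[2]])
    flat[cbind(idxPlane[, 1] + 1, idxPlane[, 2] + 1)] <- inside
    if (sliceAxis == 1) plane[k + 1, , ] <- flat
    else if (sliceAxis == 2) plane[, k + 1, ] <- flat
    else plane[, , k + 1] <- flat
    out <- xor(out, plane)
  }
  labelMask(out, reference, label = label, provenance = "manual")
}

#' Keep only the largest 6-connected component of a mask
#'
#' Optional cleanup; off by default everywhere because the study workflow
#' corrects masks manually instead.
#'
#' @param mask a [LabelMask-class].
#' @return the filtered [LabelMask-class].
#' @export
largestComponent <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- .cppComponents(as.integer(mask@voxels), dim(mask@voxels))
  if (max(lab) == 0) return(mask)
  counts <- tabulate(lab)
  keep <- which.max(counts)
  labelMask(array(lab == keep, dim(mask@voxels)), mask, label = mask@label,
            provenance = mask@provenance)
}
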