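## Reproducibility metrics: perpendicular surface distances (RMSD, MD),
## Dice similarity index, mesh voxelization, descriptive statistics.

#' Symmetric surface distances between two meshes
#'
#' For every vertex of `a` the perpendicular (nearest point-to-triangle)
#' distance to surface `b` is measured, and symmetrically from `b` to `a`;
#' RMSD is the root mean square and MD the maximum of the pooled
#' distances.  Larger values mean greater mismatch between the two models.
#'
#' @param a,b [SurfaceMesh-class] objects in one world frame (mm).
#' @param direction `"symmetric"` (pooled both ways, default) or `"a_to_b"`.
#' @param method `"grid"` (uniform-grid accelerated, default) or `"brute"`
#'   (exhaustive; the oracle both must agree with).
#' @return named numeric: `rmsd`, `md` (mm).
#' @examples
#' m <- labelMask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)),
#'                imageVolume(array(0, c(3, 3, 3))), label = "bone")
#' surfaceDistance(maskToMesh(m), maskToMesh(m))
#' @export
surfaceDistance <- function(a, b, direction = c("symmetric", "a_to_b"),
                            method = c("grid", "brute")) {
  stopifnot(is(a, "SurfaceMesh"), is(b, "SurfaceMesh"))
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (nrow(a@vertices) == 0 || nrow(b@vertices) == 0)
    stop("cannot measure distances on an empty mesh")
  dists <- .oneWayDistances(a@vertices, b, method)
  if (direction == "symmetric")
    dists <- c(dists, .oneWayDistances(b@vertices, a, method))
  c(rmsd = sqrt(mean(dists^2)), md = max(dists))
}

.oneWayDistances <- function(pts, mesh, method) {
  if (method == "brute")
    .cppSurfDistBrute(pts, mesh@vertices, mesh@triangles)
  else {
    ext <- apply(mesh@vertices, 2, function(x) diff(range(x)))
    cell <- max(max(ext) / 40, 1e-6)
    .cppSurfDistGrid(pts, mesh@vertices, mesh@triangles, cell)
  }
}

#' Dice similarity index of two masks
#'
#' `DSI = 2 |A n B| / (|A| + |B|)`, 1 for a perfect match, 0 for disjoint
#' masks; defined as 1 when both masks are empty.
#'
#' @param a,b [LabelMask-class] objects on one grid.
#' @return DSI in `[0, 1]`.
#' @examples
#' g <- imageVolume(array(0, c(2, 2, 2)))
#' m <- labelMask(array(1, c(2, 2, 2)), g, label = "bone")
#' diceIndex(m, m)
#' @export
diceIndex <- function(a, b) {
  stopifnot(is(a, "LabelMask"), is(b, "LabelMask"))
  if (!sameGeometry(a, b))
    stop("diceIndex requires masks on the identical grid")
  na <- sum(a@voxels); nb <- sum(b@voxels)
  if (na + nb == 0) return(1)
  2 * sum(a@voxels & b@voxels) / (na + nb)
}

#' Voxelize a closed mesh onto a reference grid
#'
#' A voxel is set when its centre lies inside the mesh under the even-odd
#' ray rule (rays along the third grid axis).  The mesh must be watertight;
#' open meshes are rejected with the count of their boundary edges.
#'
#' @param mesh a watertight [SurfaceMesh-class].
#' @param reference an [ImageVolume-class] or [LabelMask-class] grid.
#' @param label label for the resulting mask.
#' @return a [LabelMask-class].
#' @export
voxelizeMesh <- function(mesh, reference, label = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"))
  e <- .meshEdges(mesh)
  key <- paste(e[, 1], e[, 2])
  bad <- sum(table(key) != 2L)
  if (bad > 0)
    stop("mesh is not watertight: ", bad,
         " edges are not shared by exactly 2 triangles")
  idx <- worldToIndex(reference, mesh@vertices)
  d <- dim(voxels(reference))
  vox <- .cppVoxelize(idx, mesh@triangles, d)
  labelMask(array(vox, d), reference,
            label = if (is.null(label)) mesh@label else label,
            provenance = "edited")
}

#' Compare two models of one structure
#'
#' Accepts each model as a mask or a mesh.  Surface distances are computed
#' on the meshes (masks are meshed with [maskToMesh()]); the Dice index is
#' computed on the reference grid (meshes are voxelized with
#' [voxelizeMesh()]).
#'
#' @param a,b [LabelMask-class] or [SurfaceMesh-class] models of the same
#'   structure.
#' @param reference grid for the Dice computation; defaults to `a` when `a`
#'   is a mask.
#' @param direction distance pooling policy, see [surfaceDistance()].
#' @return a [ComparisonReport-class].
#' @export
compareModels <- function(a, b, reference = NULL,
                          direction = c("symmetric", "a_to_b")) {
  direction <- match.arg(direction)
  lab <- structureLabel(a)
  if (!identical(lab, structureLabel(b)))
    stop(sprintf("models describe different structures ('%s' vs '%s')",
                 lab, structureLabel(b)))
  if (is.null(reference)) {
    if (is(a, "LabelMask")) reference <- a
    else if (is(b, "LabelMask")) reference <- b
    else stop("a reference grid is required when both models are meshes")
  }
  meshA <- if (is(a, "SurfaceMesh")) a else maskToMesh(a)
  meshB <- if (is(b, "SurfaceMesh")) b else maskToMesh(b)
  maskA <- if (is(a, "LabelMask")) a else voxelizeMesh(a, reference)
  maskB <- if (is(b, "LabelMask")) b else voxelizeMesh(b, reference)
  sd2 <- surfaceDistance(meshA, meshB, direction = direction)
  new("ComparisonReport",
      rmsd = unname(sd2["rmsd"]), md = unname(sd2["md"]),
      dsi = diceIndex(maskA, maskB),
      volumeA = sum(maskA@voxels), volumeB = sum(maskB@voxels),
      overlap = sum(maskA@voxels & maskB@voxels),
      label = lab, directionPolicy = direction)
}

## round half away from zero (the convention of printed clinical tables,
## unlike R's banker's rounding)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

truncateDecimals <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 1e-9) / m
}

#' Descriptive statistics of a metric column
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator; 0 for
#' a single value), with the reported values rounded to a requested
#' precision.  `rounding = "half-up"` rounds half away from zero;
#' `"truncate"` drops the excess decimals, the convention of the clinical
#' software that produced the published reproducibility tables.
#'
#' @param values numeric vector (n >= 1).
#' @param precision decimals for the reported values.
#' @param rounding `"half-up"` or `"truncate"`.
#' @return a [SummaryStats-class]; raw mean/sd are retained unrounded.
#' @examples
#' descriptiveStats(c(1, 2, 3))
#' @export
descriptiveStats <- function(values, precision = 2L,
                             rounding = c("half-up", "truncate")) {
  rounding <- match.arg(rounding)
  values <- as.numeric(values)
  if (length(values) == 0) stop("no values supplied")
  if (anyNA(values)) stop("values contain NA")
  m <- mean(values)
  s <- if (length(values) == 1) 0 else stats::sd(values)
  rnd <- if (rounding == "half-up") roundHalfUp else truncateDecimals
  new("SummaryStats", mean = m, sd = s, n = length(values),
      precision = as.integer(precision), rounding = rounding,
      meanRounded = rnd(m, precision), sdRounded = rnd(s, precision))
}

#' Summarise a reproducibility table
#'
#' Takes a long-format table with one row per joint and structure
#' (columns `tmj`, `structure`, `rmsd_mm`, `md_mm`, `dsi`) and appends a
#' mean/SD row per structure, reproducing the summary row of a published
#' intra-observer variability table.
#'
#' @param df data.frame in the long layout above (see
#'   `system.file("extdata", "tmj_reproducibility.csv", package =
#'   "tmjfuse")` for a worked example: per-joint RMSD/MD/DSI of condyle,
#'   fossa and disc from a ten-joint intra-observer study).
#' @param precision named decimals per metric (defaults match the published
#'   table: rmsd 2, md 2, dsi 2).
#' @param rounding rounding mode for the summary row (default
#'   `"truncate"`, the published table's convention).
#' @return data.frame with columns structure, metric, mean, sd, n,
#'   mean_reported, sd_reported.
#' @export
summarizeReproducibility <- function(df, precision = c(rmsd_mm = 2L,
                                                       md_mm = 2L,
                                                       dsi = 2L),
                                     rounding = "truncate") {
  need <- c("structure", "rmsd_mm", "md_mm", "dsi")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (st in unique(df$structure)) {
    sub <- df[df$structure == st, ]
    for (metric in c("rmsd_mm", "md_mm", "dsi")) {
      s <- descriptiveStats(sub[[metric]], precision = precision[[metric]],
                            rounding = rounding)
      rows[[length(rows) + 1]] <- data.frame(
        structure = st, metric = metric, mean = s@mean, sd = s@sd,
        n = s@n, mean_reported = s@meanRounded, sd_reported = s@sdRounded)
    }
  }
  do.call(rbind, rows)
}
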