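## Binary masks to unsmoothed triangle surface models; STL read/write.

#' Extract the unsmoothed iso-surface of a binary mask
#'
#' Marching tetrahedra at iso-level 0.5 of the binary grid: each voxel cell
#' is split into six tetrahedra around a common diagonal (neighbouring
#' cells share face diagonals, so the mesh is watertight and manifold with
#' no ambiguous configurations); iso-vertices sit at the midpoints of edges
#' joining an inside and an outside voxel centre.  The mask is padded with
#' one background layer first so structures touching the grid border still
#' close.  No smoothing, decimation or hole filling is applied, so repeated
#' runs are bit-identical and surface distances reflect the segmentation
#' alone.
#'
#' @param mask a non-empty [LabelMask-class].
#' @return a [SurfaceMesh-class] with vertices in world mm and outward
#'   winding.
#' @examples
#' m <- labelMask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)),
#'                imageVolume(array(0, c(3, 3, 3))), label = "bone")
#' maskToMesh(m)
#' @export
maskToMesh <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  if (sum(mask@voxels) == 0) stop("cannot mesh an empty mask")
  d <- dim(mask@voxels)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask@voxels
  res <- .cppMarchingTets(as.integer(padded), dim(padded))
  idx <- res$vertices - 1   # un-pad: grid indices of the original mask
  verts <- indexToWorld(mask, idx)
  new("SurfaceMesh", vertices = verts, triangles = res$triangles,
      label = mask@label)
}

#' Signed enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for
#' outward winding.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices
  tr <- mesh@triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

## edge table: m x 2 matrix of sorted vertex index pairs, one row per
## triangle edge (3 per triangle)
.meshEdges <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is every mesh edge shared by exactly two triangles?
#' @param mesh a [SurfaceMesh-class].
#' @return logical.
#' @export
isWatertight <- function(mesh) {
  e <- .meshEdges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL: 80-byte header, uint32 triangle count, then
#' one 50-byte record per triangle (normal, three vertices, attribute
#' count).  STL carries no units; a JSON sidecar (`<path>.json`) records
#' that coordinates are mm and which structure the model is.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.stl` path.
#' @param sidecar write the units/label sidecar JSON (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSTL <- function(mesh, path, sidecar = TRUE) {
  stopifnot(is(mesh, "SurfaceMesh"))
  v <- mesh@vertices
  tr <- mesh@triangles
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- charToRaw(sprintf("%-80s", "tmjfuse binary STL (mm)"))[1:80]
  writeBin(hdr, con)
  writeBin(nrow(tr), con, size = 4, endian = "little")
  for (t in seq_len(nrow(tr))) {
    a <- v[tr[t, 1], ]; b <- v[tr[t, 2], ]; cc <- v[tr[t, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  if (sidecar)
    jsonlite::write_json(list(units = "mm", label = mesh@label,
                              triangles = nrow(tr)),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an STL mesh (binary or ASCII, sniffed)
#'
#' @param path `.stl` path.
#' @param label structure label to attach (from the sidecar if present).
#' @return a [SurfaceMesh-class].  Vertices shared between triangles are
#'   merged by exact float32 coordinate match.
#' @export
readSTL <- function(path, label = NULL) {
  if (is.null(label)) {
    sc <- paste0(path, ".json")
    label <- if (file.exists(sc))
      jsonlite::read_json(sc)$label else "bone"
  }
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not an STL file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  head84 <- readBin(con, "raw", min(84, sz))
  isAscii <- identical(rawToChar(head84[1:5]), "solid")
  if (isAscii) {
    # verify it parses as ASCII (binary files may start with 'solid' too)
    txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
    isAscii <- !is.null(txt) && any(grepl("^\\s*facet\\s+normal", txt))
    if (isAscii) return(.readAsciiSTL(txt, label))
  }
  if (sz < 84) stop("truncated binary STL: ", path)
  ntri <- readBin(head84[81:84], "integer", 1, size = 4, endian = "little")
  need <- 84 + 50 * ntri
  if (sz < need)
    stop(sprintf("corrupt binary STL: %d triangles need %d bytes, file has %d",
                 ntri, need, sz))
  rec <- readBin(con, "raw", 50 * ntri)
  # bytes 13..48 of each 50-byte record hold the 9 vertex floats
  sel <- as.vector(outer(13:48, seq(0L, by = 50L, length.out = ntri), `+`))
  vals <- readBin(rec[sel], "double", 9L * ntri, size = 4, endian = "little")
  tri <- matrix(vals, ntri, 9, byrow = TRUE)
  .assembleMesh(tri, label)
}

.readAsciiSTL <- function(txt, label) {
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) %% 3 != 0)
    stop("corrupt ASCII STL: vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  ntri <- nrow(nums) / 3
  tri <- matrix(0, ntri, 9)
  for (t in seq_len(ntri))
    tri[t, ] <- as.numeric(t(nums[(3 * t - 2):(3 * t), ]))
  .assembleMesh(tri, label)
}

.assembleMesh <- function(tri, label) {
  ntri <- nrow(tri)
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ntri, 3)
  new("SurfaceMesh", vertices = verts, triangles = tris, label = label)
}
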