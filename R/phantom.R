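## Deterministic digital TMJ phantom: paired CT-like / MR-like volumes,
## ground-truth masks and transform, and seed-controlled mask perturbations.

#' Construct a PhantomSpec
#'
#' Defaults render a stylised closed-mouth TMJ: a condylar head
#' (ellipsoid, semi-axes 6.5 x 5 x 4.5 mm, mediolaterally widest as in
#' life), a glenoid fossa shell (radii 6--8 mm,
#' dome cap) sharing its centre 7 mm below the joint space, a biconcave
#' articular disc filling 70% of the condyle-fossa gap, and a bright
#' retrodiscal ellipsoid posterior to the disc (MR only).  CT is rendered
#' at 0.25 mm isotropic over a 28 x 28 x 18 mm field; MR at 0.5 mm
#' in-plane with 10 sagittal slices of 3 mm thickness and 0.3 mm gaps.
#' Bone is 600--700 HU on CT (background soft tissue 40 HU) and dark on MR
#' (40 a.u. against 120 a.u. soft tissue); the disc is dark on MR
#' (30 a.u.), the retrodiscal region bright (200 a.u.).
#'
#' @param truthTransform ground-truth fixed-to-moving
#'   [SimilarityTransform-class]; the default displaces the MR frame by
#'   (4, -3, 2) mm and (3, -2, 5) degrees about the CT centre.
#' @param noiseSd named additive Gaussian noise SDs, `c(ct = , mr = )`;
#'   default zero (noise-free).
#' @param textureAmp amplitude of the smooth anatomical texture field
#'   rendered into both modalities (HU for CT, a.u. for MR); emulates the
#'   trabecular and soft-tissue inhomogeneity that carries alignment
#'   information away from structure boundaries in real scans.
#' @param seed integer seed for the noise draw.
#' @param ctSpacing CBCT voxel size (isotropic), mm.
#' @param ctDim CBCT grid dimensions.
#' @param mrInPlane MR in-plane spacing, mm.
#' @param mrSlice MR [SliceGeometry-class] (slices along axis 1, sagittal).
#' @param mrDim MR grid dimensions (slices first).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(truthTransform = similarityTransform(
                          rotation = c(3, -2, 5),
                          translation = c(4, -3, 2),
                          center = c(0, 0, -6)),
                        noiseSd = c(ct = 0, mr = 0),
                        textureAmp = c(ct = 15, mr = 12),
                        seed = 7L,
                        ctSpacing = 0.25,
                        ctDim = c(112L, 112L, 72L),
                        mrInPlane = 0.5,
                        mrSlice = sliceGeometry(3, 0.3, sliceAxis = 1L),
                        mrDim = c(10L, 64L, 64L)) {
  new("PhantomSpec",
      condyleCenter = c(0, 0, -7), condyleRadii = c(6.5, 5, 4.5),
      fossaCenter = c(0, 0, -7), fossaRadii = c(6, 8),
      fossaCapHeight = 3.5, discRadius = 5, discThickness = c(0.6, 1.2),
      retroCenter = c(0, 5, -5), retroRadii = c(2, 1.8, 1.2),
      ctIntensities = c(background = 40, condyle = 700, fossa = 600,
                        disc = 50),
      mrIntensities = c(background = 120, bone = 40, disc = 30,
                        retro = 200),
      textureAmp = textureAmp,
      noiseSd = noiseSd, ctSpacing = ctSpacing, ctDim = as.integer(ctDim),
      mrInPlane = mrInPlane, mrSlice = mrSlice, mrDim = as.integer(mrDim),
      truthTransform = truthTransform, seed = as.integer(seed))
}

## ---- analytic anatomy ----------------------------------------------------

.inEllipsoid <- function(p, center, radii) {
  ((p[, 1] - center[1]) / radii[1])^2 + ((p[, 2] - center[2]) / radii[2])^2 +
    ((p[, 3] - center[3]) / radii[3])^2 <= 1
}

.inCondyle <- function(spec, p)
  .inEllipsoid(p, spec@condyleCenter, spec@condyleRadii)

.inFossa <- function(spec, p) {
  d2 <- (p[, 1] - spec@fossaCenter[1])^2 + (p[, 2] - spec@fossaCenter[2])^2 +
    (p[, 3] - spec@fossaCenter[3])^2
  d2 >= spec@fossaRadii[1]^2 & d2 <= spec@fossaRadii[2]^2 &
    (p[, 3] - spec@fossaCenter[3]) >= spec@fossaCapHeight
}

## joint-space geometry along the (vertical) joint axis
.discSurfaces <- function(spec, rho) {
  # widest in-plane semi-axis: an upper bound on the condylar surface height
  # at radius rho, so the disc never touches the (anisotropic) condyle
  rxy <- max(spec@condyleRadii[1:2])
  rz <- spec@condyleRadii[3]
  top <- spec@condyleCenter[3] +
    rz * sqrt(pmax(0, 1 - (rho / rxy)^2))           # condyle upper surface
  dome <- spec@fossaCenter[3] +
    sqrt(pmax(0, spec@fossaRadii[1]^2 - rho^2))     # fossa inner surface
  list(top = top, dome = dome, gap = dome - top)
}

.inDisc <- function(spec, p) {
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  ok <- rho <= spec@discRadius
  s <- .discSurfaces(spec, pmin(rho, spec@discRadius))
  mid <- (s$top + s$dome) / 2
  tc <- spec@discThickness[1]; te <- spec@discThickness[2]
  th <- pmin(tc + (te - tc) * (rho / spec@discRadius)^2, 0.7 * s$gap)
  ok & s$gap > 0.3 & abs(p[, 3] - mid) <= th / 2
}

.inRetro <- function(spec, p)
  .inEllipsoid(p, spec@retroCenter, spec@retroRadii)

## smooth multiplicative-free anatomical texture shared by both modalities
## (trabecular / soft-tissue inhomogeneity); periods of 7-11 mm survive the
## 3 mm MR slab averaging
.anatomyTexture <- function(p) {
  sin(2 * pi * p[, 1] / 9) * cos(2 * pi * p[, 2] / 7) +
    cos(2 * pi * p[, 1] / 11) * sin(2 * pi * p[, 3] / 8)
}

## ---- partial-volume rendering --------------------------------------------

## logical array of voxels whose 6-neighbourhood is not constant
.boundaryVoxels <- function(ind) {
  d <- dim(ind)
  bd <- array(FALSE, d)
  sh <- function(a, ax, by) {
    # shift with edge replication
    i <- lapply(d, seq_len)
    i[[ax]] <- pmin(pmax(i[[ax]] + by, 1L), d[ax])
    a[i[[1]], i[[2]], i[[3]], drop = FALSE]
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    bd <- bd | (ind != sh(ind, ax, by))
  bd
}

## occupancy in [0,1] of an analytic region on a grid: voxel-centre
## indicator everywhere, refined by 3x3x3 supersampling at boundary voxels
.renderOccupancy <- function(insideFn, grid, supersample = 3L) {
  d <- grid$dim
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w <- sweep(sweep(idx, 2, grid$spacing, `*`) %*% t(grid$direction), 2,
             grid$origin, `+`)
  ind <- array(insideFn(w), d)
  occ <- array(as.numeric(ind), d)
  bd <- .boundaryVoxels(ind)
  nb <- which(bd)
  if (length(nb) > 0 && supersample > 1L) {
    off1 <- ((seq_len(supersample) - 0.5) / supersample - 0.5)
    offs <- as.matrix(expand.grid(off1, off1, off1))
    acc <- numeric(length(nb))
    base <- idx[nb, , drop = FALSE]
    for (q in seq_len(nrow(offs))) {
      pts <- sweep(base, 2, offs[q, ], `+`)
      wq <- sweep(sweep(pts, 2, grid$spacing, `*`) %*% t(grid$direction), 2,
                  grid$origin, `+`)
      acc <- acc + insideFn(wq)
    }
    occ[nb] <- acc / nrow(offs)
  }
  occ
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the digital TMJ phantom
#'
#' Renders the CT volume on its isotropic grid in the fixed frame and the
#' MR volume on its anisotropic slice grid in the frame displaced by the
#' ground-truth transform (each MR voxel averages the anatomy over its
#' 3 mm slab, so slice partial-volume is realistic).  Structure boundaries
#' are anti-aliased by supersampled occupancy; truth masks are the
#' occupancy >= 0.5 voxels on the CT grid and are verified pairwise
#' disjoint.  With a fixed spec the output is bit-identical across runs.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `ct`, `mr` ([ImageVolume-class]), `masks` (named list
#'   of condyle/fossa/disc [LabelMask-class]), `retroRegion` (the bright
#'   retrodiscal reference mask, MR contrast only), `truthTransform`, and
#'   `spec`.
#' @examples
#' ph <- generatePhantom(phantomSpec(ctDim = c(48L, 48L, 36L),
#'                                   mrDim = c(6L, 24L, 24L)))
#' ph$ct
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  ctGrid <- list(dim = spec@ctDim, spacing = rep(spec@ctSpacing, 3),
                 origin = c(0, 0, -6) -
                   (spec@ctDim - 1) / 2 * spec@ctSpacing,
                 direction = diag(3))
  occC <- .renderOccupancy(function(p) .inCondyle(spec, p), ctGrid)
  occF <- .renderOccupancy(function(p) .inFossa(spec, p), ctGrid)
  occD <- .renderOccupancy(function(p) .inDisc(spec, p), ctGrid)
  occR <- .renderOccupancy(function(p) .inRetro(spec, p), ctGrid,
                           supersample = 1L)
  ci <- spec@ctIntensities
  idxCt <- as.matrix(expand.grid(i = seq_len(spec@ctDim[1]) - 1,
                                 j = seq_len(spec@ctDim[2]) - 1,
                                 k = seq_len(spec@ctDim[3]) - 1))
  wCt <- sweep(sweep(idxCt, 2, ctGrid$spacing, `*`), 2, ctGrid$origin, `+`)
  ctVox <- ci["background"] +
    (ci["condyle"] - ci["background"]) * occC +
    (ci["fossa"] - ci["background"]) * occF +
    (ci["disc"] - ci["background"]) * occD +
    array(spec@textureAmp[["ct"]] * .anatomyTexture(wCt), spec@ctDim)
  maskC <- occC >= 0.5
  maskF <- occF >= 0.5
  maskD <- occD >= 0.5
  if (any(maskC & maskF) || any(maskC & maskD) || any(maskF & maskD))
    stop("phantom spec invalid: structure truth masks overlap")
  ctVolNoNoise <- array(as.numeric(ctVox), spec@ctDim)

  # MR in the moving frame: anatomy at Tinv(y), slab-averaged along the
  # slice axis over the slice thickness
  pitch <- spec@mrSlice@sliceThickness + spec@mrSlice@interSliceGap
  mrSpacing <- c(pitch, spec@mrInPlane, spec@mrInPlane)
  mrCenter <- applyTransform(spec@truthTransform, c(0, 0, -6))
  mrGrid <- list(dim = spec@mrDim, spacing = mrSpacing,
                 origin = mrCenter - (spec@mrDim - 1) / 2 * mrSpacing,
                 direction = diag(3))
  tinv <- invertTransform(spec@truthTransform)
  mi <- spec@mrIntensities
  mrAnatomy <- function(pFixed) {
    bone <- .inCondyle(spec, pFixed) | .inFossa(spec, pFixed)
    disc <- .inDisc(spec, pFixed)
    retro <- .inRetro(spec, pFixed)
    val <- rep(mi["background"], nrow(pFixed))
    val[retro] <- mi["retro"]
    val[disc] <- mi["disc"]
    val[bone] <- mi["bone"]   # bone wins over soft structures
    val + spec@textureAmp[["mr"]] * .anatomyTexture(pFixed)
  }
  d <- spec@mrDim
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  slabOff <- (seq_len(6) - 0.5) / 6 * spec@mrSlice@sliceThickness -
    spec@mrSlice@sliceThickness / 2
  planeOff <- c(-0.25, 0.25)
  acc <- numeric(nrow(idx))
  nsamp <- 0L
  for (sx in slabOff) for (sy in planeOff) for (sz in planeOff) {
    pts <- sweep(idx, 2, c(sx, sy * spec@mrInPlane, sz * spec@mrInPlane) /
                   c(mrSpacing[1], mrSpacing[2], mrSpacing[3]), `+`)
    wmov <- sweep(sweep(pts, 2, mrSpacing, `*`), 2, mrGrid$origin, `+`)
    pFixed <- applyTransform(tinv, wmov)
    acc <- acc + mrAnatomy(pFixed)
    nsamp <- nsamp + 1L
  }
  mrVoxNoNoise <- array(acc / nsamp, d)

  noisy <- .withSeed(spec@seed, {
    ctN <- if (spec@noiseSd[["ct"]] > 0)
      ctVolNoNoise + array(rnorm(length(ctVolNoNoise),
                                 sd = spec@noiseSd[["ct"]]), spec@ctDim)
    else ctVolNoNoise
    mrN <- if (spec@noiseSd[["mr"]] > 0)
      mrVoxNoNoise + array(rnorm(length(mrVoxNoNoise),
                                 sd = spec@noiseSd[["mr"]]), d)
    else mrVoxNoNoise
    list(ct = ctN, mr = mrN)
  })

  ct <- imageVolume(noisy$ct, spacing = ctGrid$spacing,
                    origin = ctGrid$origin, modality = "CT")
  mr <- imageVolume(noisy$mr, spacing = mrSpacing, origin = mrGrid$origin,
                    modality = "MR")
  masks <- list(
    condyle = labelMask(maskC, ct, label = "condyle", provenance = "manual"),
    fossa = labelMask(maskF, ct, label = "fossa", provenance = "manual"),
    disc = labelMask(maskD, ct, label = "disc", provenance = "manual"))
  retro <- labelMask(occR >= 0.5 & !(maskC | maskF | maskD), ct,
                     label = "disc", provenance = "manual")
  list(ct = ct, mr = mr, masks = masks, retroRegion = retro,
       truthTransform = spec@truthTransform, spec = spec)
}

## ---- seed-controlled mask perturbation -----------------------------------

## smooth noise field: iid normals on a coarse lattice, trilinearly
## upsampled, rescaled to unit RMS
.smoothNoiseField <- function(d, coarseVox) {
  nc <- pmax(2L, as.integer(ceiling((d - 1) / coarseVox) + 1L))
  g <- array(rnorm(prod(nc)), nc)
  for (ax in 1:3) {
    t <- (seq_len(d[ax]) - 1) / coarseVox
    i0 <- pmin(floor(t), nc[ax] - 2)
    w <- t - i0
    lo <- lapply(dim(g), seq_len)
    hi <- lo
    lo[[ax]] <- as.integer(i0 + 1)
    hi[[ax]] <- as.integer(i0 + 2)
    a <- g[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    b <- g[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    # broadcast the interpolation weights along the other two axes
    warr <- aperm(array(w, c(d[ax], dim(a)[-ax])),
                  order(c(ax, seq_len(3)[-ax])))
    g <- a * (1 - warr) + b * warr
  }
  g / sqrt(mean(g^2))
}

#' Seed-controlled boundary perturbation of a mask
#'
#' Emulates intra-observer re-segmentation: the mask boundary is displaced
#' by a smooth random field with RMS amplitude about `magnitude` mm.  The
#' signed Euclidean distance to the boundary is thresholded against the
#' field, so magnitude 0 reproduces the input exactly and the expected
#' Dice against the original decreases as the magnitude grows.
#'
#' @param mask a [LabelMask-class].
#' @param magnitude RMS boundary displacement, mm (>= 0).
#' @param seed integer seed; identical seed and magnitude give identical
#'   output.
#' @param correlationLength spatial scale of the displacement field, mm.
#' @return the perturbed [LabelMask-class].
#' @export
perturbMask <- function(mask, magnitude, seed = 1L,
                        correlationLength = 2) {
  stopifnot(is(mask, "LabelMask"), magnitude >= 0)
  if (magnitude == 0) return(mask)
  d <- dim(mask@voxels)
  dist2in <- .cppEdt(as.integer(mask@voxels), d, mask@spacing)
  dist2out <- .cppEdt(as.integer(1L - mask@voxels), d, mask@spacing)
  signed <- array(dist2in - dist2out, d)   # negative inside, positive outside
  coarseVox <- max(2, round(correlationLength / mean(mask@spacing)))
  g <- .withSeed(seed, .smoothNoiseField(d, coarseVox)) * magnitude
  labelMask(signed < g, mask, label = mask@label, provenance = "edited")
}
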