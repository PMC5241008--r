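## Mutual-information similarity on a joint intensity histogram, Powell's
## conjugate-direction optimiser, and the two-stage rigid MRI -> CBCT
## registration.

#' Joint intensity histogram of a fixed/moving volume pair
#'
#' Visits fixed-grid voxel centres (optionally with a stride), maps each
#' through `transform` into the moving volume, interpolates the moving
#' intensity linearly, and bins the pair.  Bin edges are equal-width over
#' each volume's full observed intensity range; only in-bounds pairs are
#' counted.
#'
#' @param fixed,moving [ImageVolume-class] objects.
#' @param transform fixed-to-moving world [SimilarityTransform-class].
#' @param bins bins per axis (>= 2); default 64.
#' @param stride fixed-grid sampling stride (1 = every voxel).
#' @return a [JointHistogram-class].
#' @examples
#' v <- imageVolume(array(c(0, 0, 1, 1), c(1, 1, 4)))
#' w <- imageVolume(array(c(1, 1, 0, 0), c(1, 1, 4)))
#' h <- computeJointHistogram(v, w, bins = 2)
#' h@counts
#' @export
computeJointHistogram <- function(fixed, moving,
                                  transform = similarityTransform(),
                                  bins = 64L, stride = 1L) {
  stopifnot(is(fixed, "ImageVolume"), is(moving, "ImageVolume"))
  if (bins < 2L) stop("bins must be >= 2")
  fr <- range(fixed@voxels, na.rm = TRUE)
  mrg <- range(moving@voxels, na.rm = TRUE)
  if (fr[2] <= fr[1]) fr[2] <- fr[1] + 1
  if (mrg[2] <= mrg[1]) mrg[2] <- mrg[1] + 1
  A <- indexToIndexAffine(fixed, moving, transform)
  fv <- fixed@voxels
  if (anyNA(fv)) fv[is.na(fv)] <- fr[1]
  mv <- moving@voxels
  hasNA <- anyNA(mv)
  if (hasNA) mv[is.na(mv)] <- NA_real_  # NA propagates to skip via interp
  res <- .cppJointHist(as.numeric(fv), dim(fv), as.numeric(mv), dim(mv), A,
                       as.integer(bins), fr[1], fr[2], mrg[1], mrg[2],
                       as.integer(stride))
  frac <- res$n / res$visited
  if (frac < 0.01)
    stop(sprintf("volumes overlap for only %.2f%% of fixed voxels under this transform",
                 100 * frac))
  new("JointHistogram",
      counts = res$counts,
      edgesFixed = seq(fr[1], fr[2], length.out = bins + 1),
      edgesMoving = seq(mrg[1], mrg[2], length.out = bins + 1),
      nSamples = res$n)
}

#' @describeIn computeJointHistogram joint probability mass function p(x, y).
#' @param h a [JointHistogram-class].
#' @export
jointPmf <- function(h) {
  if (h@nSamples <= 0) stop("empty histogram")
  h@counts / h@nSamples
}

#' @describeIn computeJointHistogram marginal pmf of the fixed intensities.
#' @export
marginalFixed <- function(h) rowSums(jointPmf(h))

#' @describeIn computeJointHistogram marginal pmf of the moving intensities.
#' @export
marginalMoving <- function(h) colSums(jointPmf(h))

.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint histogram (bits)
#'
#' `MI = sum_xy p(x,y) log2( p(x,y) / (p(x) p(y)) )`, with `0 log 0 = 0`.
#' Non-negative, symmetric in the two axes, and zero exactly when the joint
#' distribution factorises into its marginals.
#'
#' @param h a [JointHistogram-class] (or a joint pmf matrix).
#' @return mutual information in bits.
#' @export
mutualInformation <- function(h) {
  p <- if (is(h, "JointHistogram")) jointPmf(h) else h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  .entropyBits(px) + .entropyBits(py) - .entropyBits(p)
}

#' Normalised mutual information of a joint histogram
#'
#' The overlap-invariant form `NMI = (H(X) + H(Y)) / H(X, Y)`, ranging over
#' (1, 2]: 1 for independent intensities, 2 for a deterministic one-to-one
#' correspondence.
#'
#' @param h a [JointHistogram-class] (or a joint pmf matrix).
#' @return dimensionless NMI.
#' @export
normalizedMutualInformation <- function(h) {
  p <- if (is(h, "JointHistogram")) jointPmf(h) else h / sum(h)
  hx <- .entropyBits(rowSums(p)); hy <- .entropyBits(colSums(p))
  if (hx <= 0 || hy <= 0)
    stop("constant image: a marginal entropy is zero, NMI undefined")
  (hx + hy) / .entropyBits(p)
}

#' Powell's conjugate-direction maximisation
#'
#' Derivative-free maximisation by successive line searches (Brent's method
#' via [stats::optimize]) along a direction set that is updated each cycle
#' with the overall displacement direction (Powell's heuristic, with the
#' standard replacement tests).  Terminates when a full cycle improves the
#' objective by less than `tol` in relative terms, or after `maxCycles`.
#'
#' @param objective function of a parameter vector, to be maximised.
#' @param start numeric start vector.
#' @param directions initial direction set (matrix, one direction per
#'   column); defaults to the coordinate axes.
#' @param tol relative improvement tolerance ending the cycle loop.
#' @param maxCycles cycle cap.
#' @param lineHalfWidth half-width (same units as the parameters) of the
#'   bracketing interval handed to each 1-D line search.
#' @param lineTol absolute x-tolerance of each line search.
#' @return list with `par`, `value`, `cycles`, `converged`, and `nEval`.
#' @examples
#' f <- function(p) -sum((p - c(1, 2))^2)
#' optimizePowell(f, c(0, 0))$par
#' @export
optimizePowell <- function(objective, start, directions = NULL, tol = 1e-6,
                           maxCycles = 50L, lineHalfWidth = 2,
                           lineTol = 1e-4) {
  n <- length(start)
  f0 <- objective(start)
  if (!is.finite(f0)) stop("objective is not finite at the start point")
  dirs <- if (is.null(directions)) diag(n) else as.matrix(directions)
  p <- start
  fp <- f0
  nEval <- 1L
  cycles <- 0L
  converged <- FALSE
  lineMax <- function(p0, f0, d) {
    nd <- sqrt(sum(d^2))
    if (nd < 1e-15) return(list(par = p0, value = f0))
    d <- d / nd
    g <- function(a) { nEval <<- nEval + 1L; objective(p0 + a * d) }
    # bracket a local maximum by outward expansion from the current point
    h <- lineHalfWidth / 8
    f1 <- g(h)
    if (f1 < f0) {
      h <- -h
      f1 <- g(h)
    }
    if (f1 < f0) {
      lo <- -abs(h); hi <- abs(h)       # maximum near 0
    } else {
      a <- 0; b <- h; fb <- f1
      repeat {
        cc <- 2 * b
        if (abs(cc) > lineHalfWidth) { cc <- sign(b) * lineHalfWidth }
        fc <- g(cc)
        if (fc < fb || abs(cc) >= lineHalfWidth) { a <- a; b <- cc; break }
        a <- b; b <- cc; fb <- fc
      }
      lo <- min(0, b); hi <- max(0, b)
    }
    opt <- stats::optimize(g, c(lo, hi), maximum = TRUE, tol = lineTol)
    if (opt$objective >= f0)
      list(par = p0 + opt$maximum * d, value = opt$objective)
    else list(par = p0, value = f0)
  }
  while (cycles < maxCycles) {
    cycles <- cycles + 1L
    pStart <- p
    fStart <- fp
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      res <- lineMax(p, fp, dirs[, i])
      if (res$value - fp > biggest) {
        biggest <- res$value - fp
        ibig <- i
      }
      p <- res$par
      fp <- res$value
    }
    if (2 * (fp - fStart) <= tol * (abs(fp) + abs(fStart)) + 1e-15) {
      converged <- TRUE
      break
    }
    # Powell direction-replacement tests (extrapolated point)
    pe <- 2 * p - pStart
    fe <- objective(pe)
    nEval <- nEval + 1L
    if (fe > fStart) {
      t <- 2 * (fStart - 2 * fp + fe) * (fStart - fp - biggest)^2 -
        biggest * (fStart - fe)^2
      if (t < 0) {
        res <- lineMax(p, fp, p - pStart)
        p <- res$par
        fp <- res$value
        dirs[, ibig] <- dirs[, n]
        dirs[, n] <- (p - pStart) / max(sqrt(sum((p - pStart)^2)), 1e-15)
      }
    }
  }
  list(par = p, value = fp, cycles = cycles, converged = converged,
       nEval = nEval)
}

## similarity of a parameter vector p = (pitch, roll, yaw, tx, ty, tz[, s])
.regObjective <- function(fixed, moving, kind, bins, stride, center,
                          traceEnv, stage) {
  fr <- range(fixed@voxels)
  mrg <- range(moving@voxels)
  if (fr[2] <= fr[1] || mrg[2] <= mrg[1])
    stop("registration requires non-constant volumes")
  function(p) {
    tr <- similarityTransform(rotation = p[1:3], translation = p[4:6],
                              scale = if (length(p) >= 7) exp(p[7]) else 1,
                              center = center)
    A <- indexToIndexAffine(fixed, moving, tr)
    res <- .cppJointHist(as.numeric(fixed@voxels), dim(fixed@voxels),
                         as.numeric(moving@voxels), dim(moving@voxels), A,
                         as.integer(bins), fr[1], fr[2], mrg[1], mrg[2],
                         as.integer(stride))
    if (res$n < 0.01 * res$visited) return(-Inf)
    pmf <- res$counts / res$n
    val <- if (kind == "NMI") {
      hx <- .entropyBits(rowSums(pmf)); hy <- .entropyBits(colSums(pmf))
      if (hx <= 0 || hy <= 0) return(-Inf)
      (hx + hy) / .entropyBits(pmf)
    } else {
      mutualInformation(pmf * res$n)
    }
    i <- traceEnv$i <- traceEnv$i + 1L
    traceEnv$rows[[i]] <- c(stage, p[1:6], val)
    val
  }
}

#' Rigid registration of a moving MR volume onto a fixed CBCT volume
#'
#' Maximises (normalised) mutual information over rotation and translation
#' (optionally isotropic scale) with Powell's method, in two stages: a fast
#' coarse stage sampling the fixed grid with a stride, then a fine stage at
#' full resolution.  Initialisation aligns the intensity centroids of the
#' two volumes; the rotation centre is the fixed volume's centre.
#'
#' @param fixed the fixed (CBCT) [ImageVolume-class].
#' @param moving the moving (MR) [ImageVolume-class]; its native anisotropic
#'   grid is used directly (linear interpolation across the slice pitch).
#' @param similarity `"nmi"` (Studholme overlap-invariant form, default) or
#'   `"mi"` (bits).
#' @param bins joint-histogram bins per axis.
#' @param freeScale estimate the isotropic scale too (default `FALSE`:
#'   rigid, scale frozen at 1).
#' @param stage1Stride,stage1Tol coarse stage: fixed-grid stride and Powell
#'   relative tolerance.
#' @param stage2Tol fine stage Powell relative tolerance (stride 1).
#' @param maxCycles Powell cycle cap per stage.
#' @return a [RegistrationResult-class]; its transform maps fixed world
#'   coordinates into moving world coordinates.
#' @export
registerVolumes <- function(fixed, moving, similarity = c("nmi", "mi"),
                            bins = 64L, freeScale = FALSE,
                            stage1Stride = 4L, stage1Tol = 1e-2,
                            stage2Tol = 1e-4, maxCycles = 50L) {
  stopifnot(is(fixed, "ImageVolume"), is(moving, "ImageVolume"))
  similarity <- match.arg(similarity)
  kind <- toupper(similarity)
  if (diff(range(fixed@voxels)) == 0 || diff(range(moving@voxels)) == 0)
    stop("registration requires non-constant volumes")
  center <- volumeCenter(fixed)
  t0 <- .intensityCentroid(moving) - .intensityCentroid(fixed)
  p <- c(0, 0, 0, t0)
  if (freeScale) p <- c(p, 0)   # log-scale parameter
  traceEnv <- new.env()
  traceEnv$i <- 0L
  traceEnv$rows <- vector("list", 20000L)
  stages <- list(
    list(stride = as.integer(stage1Stride), tol = stage1Tol,
         halfWidth = 8, lineTol = 5e-3),
    list(stride = 1L, tol = stage2Tol, halfWidth = 1.5, lineTol = 2e-4))
  nIter <- integer(0)
  converged <- TRUE
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    obj <- .regObjective(fixed, moving, kind, bins, st$stride, center,
                         traceEnv, s)
    res <- optimizePowell(obj, p, tol = st$tol, maxCycles = maxCycles,
                          lineHalfWidth = st$halfWidth,
                          lineTol = st$lineTol)
    p <- res$par
    nIter <- c(nIter, res$cycles)
    converged <- converged && res$converged
  }
  transform <- similarityTransform(rotation = p[1:3], translation = p[4:6],
                                   scale = if (freeScale) exp(p[7]) else 1,
                                   center = center)
  finalH <- computeJointHistogram(fixed, moving, transform, bins = bins)
  finalVal <- if (kind == "NMI") normalizedMutualInformation(finalH)
    else mutualInformation(finalH)
  tr <- traceEnv$rows[seq_len(traceEnv$i)]
  trace <- as.data.frame(do.call(rbind, tr))
  names(trace) <- c("stage", "pitch", "roll", "yaw", "tx", "ty", "tz",
                    "similarity")
  new("RegistrationResult", transform = transform,
      finalSimilarity = finalVal, similarityKind = kind,
      nIterations = nIter, converged = converged, trace = trace)
}

.intensityCentroid <- function(vol) {
  v <- vol@voxels
  w <- v - min(v)
  d <- dim(v)
  tot <- sum(w)
  if (tot <= 0) return(volumeCenter(vol))
  wx <- apply(w, 1, sum); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
  idx <- c(sum(wx * (seq_len(d[1]) - 1)) / tot,
           sum(wy * (seq_len(d[2]) - 1)) / tot,
           sum(wz * (seq_len(d[3]) - 1)) / tot)
  indexToWorld(vol, idx)
}

#' Serialise a transform to JSON
#'
#' @param transform a [SimilarityTransform-class].
#' @param path output JSON path.
#' @return `path` invisibly; `readTransform` returns the transform.
#' @export
writeTransform <- function(transform, path) {
  obj <- list(rotation_deg = transform@rotation,
              translation_mm = transform@translation,
              scale = transform@scale,
              center_mm = transform@center,
              convention = "intrinsic-xyz-LPS")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarityTransform(rotation = obj$rotation_deg,
                      translation = obj$translation_mm,
                      scale = obj$scale, center = obj$center_mm)
}
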