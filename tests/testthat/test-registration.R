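# Joint histograms, (normalised) mutual information, Powell, registration.

test_that("joint histogram counts match hand enumeration", {
  a <- imageVolume(array(c(0, 0, 1, 1), c(1, 1, 4)))
  b <- imageVolume(array(c(1, 1, 0, 0), c(1, 1, 4)))
  h <- computeJointHistogram(a, b, bins = 2)
  expect_equal(h@nSamples, 4)
  expect_equal(unname(h@counts), matrix(c(0, 2, 2, 0), 2, 2))
  # self-alignment of a 2-level image concentrates on the diagonal
  h2 <- computeJointHistogram(a, a, bins = 2)
  expect_equal(unname(h2@counts), matrix(c(2, 0, 0, 2), 2, 2))
  # marginals renormalise to 1 regardless of overlap
  tr <- similarityTransform(translation = c(0, 0, 1))
  h3 <- computeJointHistogram(a, b, tr, bins = 2)
  expect_lt(abs(sum(jointPmf(h3)) - 1), 1e-12)
  expect_lt(max(abs(marginalFixed(h3) - rowSums(jointPmf(h3)))), 1e-12)
  expect_lt(max(abs(marginalMoving(h3) - colSums(jointPmf(h3)))), 1e-12)
  # empty overlap is an error naming the overlap fraction
  far <- similarityTransform(translation = c(0, 0, 1000))
  expect_error(computeJointHistogram(a, b, far, bins = 2), "overlap")
})

test_that("MI and NMI match the direct-summation oracle", {
  # independent oracle: evaluate the double sum over the 2x2 pmf directly
  p <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  px <- rowSums(p); py <- colSums(p)
  miOracle <- sum(p * log2(p / outer(px, py)))
  hxy <- -sum(p * log2(p))
  expect_lt(abs(mutualInformation(p) - miOracle), 1e-12)
  expect_lt(abs(mutualInformation(p) - 0.278072), 1e-6)
  expect_lt(abs(normalizedMutualInformation(p) - 2 / hxy), 1e-12)
  # independence: MI = 0, NMI = 1
  ind <- outer(c(0.3, 0.7), c(0.6, 0.4))
  expect_lt(abs(mutualInformation(ind)), 1e-12)
  expect_lt(abs(normalizedMutualInformation(ind) - 1), 1e-12)
  # 4-level uniform image with itself: MI = H(X) = 2 bits, NMI = 2
  v4 <- imageVolume(array(rep(0:3, 16), c(4, 4, 4)))
  h4 <- computeJointHistogram(v4, v4, bins = 4)
  expect_lt(abs(mutualInformation(h4) - 2), 1e-9)
  expect_lt(abs(normalizedMutualInformation(h4) - 2), 1e-9)
  # constant image: NMI undefined
  expect_error(normalizedMutualInformation(matrix(c(1, 0, 0, 0), 2, 2)),
               "constant")
})

test_that("MI is symmetric and invariant under bin relabelling", {
  set.seed(9)
  for (i in 1:20) {
    counts <- matrix(rpois(36, 3), 6, 6)
    counts[1, 1] <- counts[1, 1] + 1  # non-empty
    expect_lt(abs(mutualInformation(counts) - mutualInformation(t(counts))),
              1e-12)
    perm <- sample(6)
    expect_lt(abs(mutualInformation(counts) -
                    mutualInformation(counts[perm, ])), 1e-12)
    expect_lt(abs(mutualInformation(counts) -
                    mutualInformation(counts[, perm])), 1e-12)
    expect_gte(mutualInformation(counts), -1e-12)
  }
})

test_that("Powell maximises standard test functions without derivatives", {
  quad <- function(p) -sum((p - c(1, 2, 3))^2)
  r <- optimizePowell(quad, c(0, 0, 0), lineHalfWidth = 5)
  expect_lt(max(abs(r$par - c(1, 2, 3))), 1e-6)
  expect_gte(r$value, quad(c(0, 0, 0)))
  # negative Rosenbrock from the classic start, grid-refined optimum (1,1)
  rosen <- function(p) -((1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2)
  r2 <- optimizePowell(rosen, c(-1.2, 1), lineHalfWidth = 2, tol = 1e-12,
                       maxCycles = 500, lineTol = 1e-8)
  expect_lt(max(abs(r2$par - c(1, 1))), 1e-4)
  # tol = Inf returns the start after one cycle
  r3 <- optimizePowell(quad, c(0.5, 0.5, 0.5), tol = Inf)
  expect_equal(r3$cycles, 1L)
  expect_error(optimizePowell(function(p) NaN, c(0)), "finite")
})

test_that("similarity peaks at the ground-truth translation on the phantom", {
  ph <- smallPhantom(truthTransform = similarityTransform(center = c(0, 0, -6)))
  vals <- vapply(seq(-5, 5, by = 0.25), function(tx) {
    tr <- similarityTransform(translation = c(tx, 0, 0))
    normalizedMutualInformation(
      computeJointHistogram(ph$ct, ph$mr, tr, bins = 64, stride = 2L))
  }, 0)
  expect_equal(seq(-5, 5, by = 0.25)[which.max(vals)], 0)
})

test_that("self-registration recovers the identity", {
  ph <- smallPhantom()
  reg <- registerVolumes(ph$ct, ph$ct, stage1Stride = 2L)
  expect_true(reg@converged)
  expect_lt(max(abs(reg@transform@rotation)), 0.05)
  expect_lt(max(abs(reg@transform@translation)), 0.05)
  expect_equal(reg@similarityKind, "NMI")
  # reported similarity equals the value recomputed from the transform
  h <- computeJointHistogram(ph$ct, ph$ct, reg@transform, bins = 64)
  expect_lt(abs(normalizedMutualInformation(h) - reg@finalSimilarity), 1e-9)
  expect_gt(nrow(reg@trace), 0)
})

test_that("registering a pre-transformed copy composes to the identity", {
  ph <- smallPhantom()
  truth <- similarityTransform(rotation = c(0, 0, 1.5),
                               translation = c(2, -1.5, 1),
                               center = c(0, 0, -6))
  # moving(y) = fixed(T(y)), so the estimated fixed->moving map is T^-1
  moving <- resampleToGrid(ph$ct, ph$ct, truth)
  vox <- voxels(moving)
  vox[is.na(vox)] <- min(vox, na.rm = TRUE)
  moving <- imageVolume(vox, spacing = spacing(moving),
                        origin = origin(moving),
                        direction = direction(moving))
  reg <- registerVolumes(ph$ct, moving, stage1Stride = 2L)
  resid <- composeTransforms(truth, reg@transform)
  expect_lt(max(abs(resid@rotation)), 0.3)
  expect_lt(max(abs(resid@translation)), 0.3)
})

test_that("transform JSON serialisation round-trips", {
  td <- withr::local_tempdir()
  tr <- similarityTransform(rotation = c(3, -2, 5), translation = c(4, -3, 2),
                            center = c(0, 0, -6))
  p <- file.path(td, "t.json")
  writeTransform(tr, p)
  tr2 <- readTransform(p)
  expect_equal(tr2@rotation, tr@rotation)
  expect_equal(tr2@translation, tr@translation)
  expect_equal(tr2@center, tr@center)
  expect_equal(tr2@scale, tr@scale)
})
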