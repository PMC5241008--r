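# Digital TMJ phantom and seed-controlled perturbations.

test_that("the phantom is deterministic and anatomically consistent", {
  ph <- defaultPhantom()
  ph2 <- generatePhantom(phantomSpec())
  expect_identical(voxels(ph$ct), voxels(ph2$ct))
  expect_identical(voxels(ph$mr), voxels(ph2$mr))
  # acquisition geometry as specified
  expect_equal(spacing(ph$ct), rep(0.25, 3))
  expect_equal(spacing(ph$mr), c(3.3, 0.5, 0.5))
  # structures pairwise disjoint, all non-empty
  m <- lapply(ph$masks, voxels)
  expect_gt(sum(m$condyle), 0)
  expect_gt(sum(m$fossa), 0)
  expect_gt(sum(m$disc), 0)
  expect_equal(sum(m$condyle & m$fossa), 0)
  expect_equal(sum(m$condyle & m$disc), 0)
  expect_equal(sum(m$fossa & m$disc), 0)
  # disc lies between condyle and fossa along the joint axis near the axis
  zs <- function(mm) range(which(apply(mm, 3, sum) > 0))
  expect_gt(zs(m$disc)[1], zs(m$condyle)[1])
  expect_lt(zs(m$disc)[2], zs(m$fossa)[2])
})

test_that("noise is seed-controlled with no hidden global randomness", {
  spec <- phantomSpec(noiseSd = c(ct = 10, mr = 4),
                      ctDim = c(40L, 40L, 30L), mrDim = c(6L, 24L, 24L))
  set.seed(123)
  before <- .Random.seed
  a <- generatePhantom(spec)
  expect_identical(.Random.seed, before)   # global RNG state untouched
  b <- generatePhantom(spec)
  expect_identical(voxels(a$ct), voxels(b$ct))
  c2 <- generatePhantom(phantomSpec(noiseSd = c(ct = 10, mr = 4), seed = 8L,
                                    ctDim = c(40L, 40L, 30L),
                                    mrDim = c(6L, 24L, 24L)))
  expect_false(identical(voxels(a$ct), voxels(c2$ct)))
})

test_that("the disc is dark on MR relative to the retrodiscal tissue", {
  ph <- generatePhantom(phantomSpec(
    truthTransform = similarityTransform(center = c(0, 0, -6))))
  mrOnCt <- resampleToGrid(ph$mr, ph$ct)
  v <- voxels(mrOnCt)
  discMean <- mean(v[voxels(ph$masks$disc) == 1], na.rm = TRUE)
  retroMean <- mean(v[voxels(ph$retroRegion) == 1], na.rm = TRUE)
  expect_lt(discMean, retroMean)
  # and dark relative to surrounding soft tissue overall
  expect_lt(discMean,
            mean(v[voxels(ph$masks$condyle) == 0 &
                     voxels(ph$masks$fossa) == 0 &
                     voxels(ph$masks$disc) == 0], na.rm = TRUE))
})

test_that("thresholding the phantom CT recovers the bone truth masks", {
  ph <- defaultPhantom()
  bone <- thresholdSegment(ph$ct, 300, 1000)
  truth <- labelMask(voxels(ph$masks$condyle) | voxels(ph$masks$fossa),
                     ph$ct, label = "bone")
  expect_gte(diceIndex(bone, truth), 0.99)
})

test_that("perturbMask is the identity at magnitude 0 and seed-stable", {
  mask <- ballMask(2, spacing = 0.25)
  expect_identical(voxels(perturbMask(mask, 0, seed = 3)), voxels(mask))
  p1 <- perturbMask(mask, 0.3, seed = 3)
  p2 <- perturbMask(mask, 0.3, seed = 3)
  expect_identical(voxels(p1), voxels(p2))
  expect_false(identical(voxels(p1),
                         voxels(perturbMask(mask, 0.3, seed = 4))))
  expect_lt(diceIndex(mask, p1), 1)
})

test_that("expected Dice decreases with perturbation magnitude", {
  mask <- ballMask(5, spacing = 0.5)
  meanDice <- vapply(c(0.1, 0.3, 0.6), function(mag) {
    mean(vapply(1:10, function(s) diceIndex(mask,
                                            perturbMask(mask, mag, s)), 0))
  }, 0)
  expect_true(all(diff(meanDice) < 0))
})
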