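# Threshold segmentation, mask editing, oriented crop box, disc contours.

test_that("thresholdSegment marks the closed HU interval", {
  ct <- imageVolume(array(c(0, 400, 1200, 300, 1000, -1000, 299, 1001, 500),
                          c(3, 3, 1)))
  m <- thresholdSegment(ct, 300, 1000)
  expect_identical(provenance(m), "threshold")
  expect_equal(sum(voxels(m)), 4)   # 400, 300, 1000, 500
  expect_true(all(voxels(m)[c(2, 4, 5, 9)] == 1))
  # unbounded window selects everything; all-background selects nothing
  expect_equal(sum(voxels(thresholdSegment(ct, -Inf, Inf))), 9)
  bg <- imageVolume(array(-1000, c(3, 3, 3)))
  expect_equal(sum(voxels(thresholdSegment(bg))), 0)
  # monotone: widening the window never removes voxels
  set.seed(21)
  ctr <- imageVolume(array(runif(125, -500, 1500), c(5, 5, 5)))
  inner <- voxels(thresholdSegment(ctr, 300, 1000))
  outer <- voxels(thresholdSegment(ctr, 200, 1100))
  expect_true(all(outer[inner == 1] == 1))
  # non-CT input rejected
  mr <- imageVolume(array(0, c(2, 2, 2)), modality = "MR")
  expect_error(thresholdSegment(mr), "CT")
})

test_that("editMask applies additions then erasures, erasure winning", {
  g <- imageVolume(array(0, c(3, 3, 3)))
  base <- labelMask(array(c(rep(1, 10), rep(0, 17)), c(3, 3, 3)), g)
  none <- labelMask(array(0, c(3, 3, 3)), g)
  expect_identical(voxels(editMask(base, none, none)), voxels(base))
  comp <- labelMask(1 - voxels(base), g)
  expect_true(all(voxels(editMask(base, comp, none)) == 1))
  both <- labelMask(array(c(1, rep(0, 26)), c(3, 3, 3)), g)
  out <- editMask(base, both, both)
  expect_equal(voxels(out)[1], 0L)          # erased despite being added
  expect_identical(provenance(out), "edited")
  # idempotent for fixed additions/erasures
  out2 <- editMask(out, both, both)
  expect_identical(voxels(out2), voxels(editMask(out2, both, both)))
  # geometry mismatch rejected
  g2 <- imageVolume(array(0, c(3, 3, 3)), origin = c(1, 0, 0))
  expect_error(editMask(base, labelMask(array(0, c(3, 3, 3)), g2), none),
               "geometry")
})

test_that("applyCrop keeps voxel centres inside the oriented box", {
  g <- imageVolume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  full <- labelMask(array(1, c(10, 10, 10)), g)
  # axis-aligned box over the left half: per-voxel point-in-box oracle
  box <- cropBox(center = c(2, 4.5, 4.5), extents = c(5, 10, 10))
  cropped <- applyCrop(full, box)
  expect_equal(sum(voxels(cropped)), 500)
  expect_true(all(which(voxels(cropped) == 1, arr.ind = TRUE)[, 1] <= 5))
  # whole-grid box is the identity; crop never adds voxels; idempotent
  whole <- cropBox(center = c(4.5, 4.5, 4.5), extents = c(30, 30, 30))
  expect_identical(voxels(applyCrop(full, whole)), voxels(full))
  expect_identical(voxels(applyCrop(cropped, box)), voxels(cropped))
  # 90 degree yaw: the footprint rotates with the box
  rot <- cropBox(center = c(4.5, 4.5, 4.5), extents = c(4, 8, 8),
                 orientation = c(0, 0, 90))
  swapped <- cropBox(center = c(4.5, 4.5, 4.5), extents = c(8, 4, 8))
  expect_equal(sum(voxels(applyCrop(full, rot))),
               sum(voxels(applyCrop(full, swapped))))
  # empty intersection warns and returns an empty mask
  off <- cropBox(center = c(100, 100, 100), extents = c(2, 2, 2))
  expect_warning(out <- applyCrop(full, off), "empty")
  expect_equal(sum(voxels(out)), 0)
})

test_that("crop box serialisation reproduces the identical box", {
  td <- withr::local_tempdir()
  box <- cropBox(center = c(1.25, -3.5, 7.125), extents = c(25, 25, 25),
                 orientation = c(12.5, -3.25, 41.0))
  p <- file.path(td, "box.json")
  writeCropBox(box, p)
  b2 <- readCropBox(p)
  expect_identical(b2@center, box@center)
  expect_identical(b2@extents, box@extents)
  expect_identical(b2@orientation, box@orientation)
})

test_that("contoursToMask rasterises closed polygons per slice", {
  ref <- imageVolume(array(0, c(8, 8, 4)), spacing = c(1, 1, 1))
  sq <- matrix(c(1.5, 1.5, 3.5, 1.5, 3.5, 3.5, 1.5, 3.5), ncol = 2,
               byrow = TRUE)
  m <- contoursToMask(list(list(sliceIndex = 1, points = sq)), ref,
                      sliceAxis = 3)
  expect_equal(sum(voxels(m)), 4)   # even-odd point-in-polygon oracle
  expect_identical(provenance(m), "manual")
  # slice independence: same polygon on two slices doubles the count
  m2 <- contoursToMask(list(list(sliceIndex = 1, points = sq),
                            list(sliceIndex = 2, points = sq)), ref,
                       sliceAxis = 3)
  expect_equal(sum(voxels(m2)), 8)
  # vertex-order reversal changes nothing
  m3 <- contoursToMask(list(list(sliceIndex = 1,
                                 points = sq[rev(seq_len(nrow(sq))), ])),
                       ref, sliceAxis = 3)
  expect_identical(voxels(m3), voxels(m))
  # explicit closure (first = last) is accepted
  m4 <- contoursToMask(list(list(sliceIndex = 1, points = rbind(sq, sq[1, ]))),
                       ref, sliceAxis = 3)
  expect_identical(voxels(m4), voxels(m))
  # empty contour list gives an empty mask
  expect_equal(sum(voxels(contoursToMask(list(), ref))), 0)
  # self-intersecting polygons are rejected with a diagnostic
  bow <- matrix(c(0, 0, 2, 2, 2, 0, 0, 2), ncol = 2, byrow = TRUE)
  expect_error(contoursToMask(list(list(sliceIndex = 0, points = bow)), ref,
                              sliceAxis = 3), "self-intersecting")
  expect_error(contoursToMask(list(list(sliceIndex = 9, points = sq)), ref,
                              sliceAxis = 3), "out of range")
})
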