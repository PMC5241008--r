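# Volume model, geometry, file I/O, gap filling and resampling.

test_that("index/world mappings match the affine definition and invert", {
  v <- imageVolume(array(0, c(8, 8, 8)), spacing = c(0.25, 0.25, 0.25))
  expect_equal(indexToWorld(v, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(indexToWorld(v, c(4, 0, 0)), c(1, 0, 0))
  set.seed(11)
  for (i in 1:10) {
    vol <- imageVolume(array(0, c(4, 5, 6)),
                       spacing = runif(3, 0.1, 3),
                       origin = runif(3, -10, 10),
                       direction = eulerToMatrix(runif(3, -180, 180)))
    p <- matrix(runif(30, -20, 20), 10, 3)
    expect_lt(max(abs(worldToIndex(vol, indexToWorld(vol, p)) - p)), 1e-9)
    expect_lt(max(abs(indexToWorld(vol, worldToIndex(vol, p)) - p)), 1e-9)
  }
})

test_that("transforms compose, invert, and respect the Euler convention", {
  tr <- similarityTransform(rotation = c(3, -2, 5), translation = c(4, -3, 2),
                            center = c(1, -1, 2))
  id <- composeTransforms(invertTransform(tr), tr)
  expect_lt(max(abs(id@rotation)), 1e-9)
  expect_lt(max(abs(id@translation)), 1e-9)
  expect_lt(abs(id@scale - 1), 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- randomTransform()
    b <- randomTransform()
    x <- matrix(runif(15, -10, 10), 5, 3)
    expect_lt(max(abs(applyTransform(composeTransforms(a, b), x) -
                        applyTransform(a, applyTransform(b, x)))), 1e-9)
    # Euler extraction recovers the matrix
    expect_lt(max(abs(eulerToMatrix(matrixToEuler(rotationMatrix(a))) -
                        rotationMatrix(a))), 1e-9)
  }
})

test_that("NIfTI and MetaImage round trips are lossless", {
  td <- withr::local_tempdir()
  set.seed(2)
  v <- imageVolume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   spacing = c(0.25, 0.5, 3.3), origin = c(-3, 2, 7),
                   modality = "MR")
  for (f in c("v.nii.gz", "v.nii", "v.mha", "v.mhd")) {
    p <- file.path(td, f)
    writeVolume(v, p)
    v2 <- readVolume(p, modality = "MR")
    expect_identical(voxels(v2), voxels(v))
    expect_lt(max(abs(spacing(v2) - spacing(v))), 1e-6)
    expect_lt(max(abs(origin(v2) - origin(v))), 1e-6)
    expect_lt(max(abs(direction(v2) - direction(v))), 1e-6)
  }
  # constant-zero volume
  z <- imageVolume(array(0, c(2, 2, 2)))
  writeVolume(z, file.path(td, "z.nii"))
  expect_true(all(voxels(readVolume(file.path(td, "z.nii"))) == 0))
  expect_error(writeVolume(v, file.path(td, "v.xyz")), "unsupported")
})

test_that("DICOM series round trip preserves voxels and geometry", {
  td <- withr::local_tempdir()
  set.seed(3)
  v <- imageVolume(array(sample(-200:1200, 4 * 4 * 5, TRUE), c(4, 4, 5)),
                   spacing = c(0.25, 0.25, 0.25), origin = c(1, -2, 3))
  dd <- file.path(td, "series")
  writeDicomSeries(v, dd)
  v2 <- readVolume(dd)
  expect_identical(voxels(v2), voxels(v))
  expect_equal(spacing(v2), c(0.25, 0.25, 0.25), tolerance = 1e-9)
  expect_lt(max(abs(origin(v2) - origin(v))), 1e-6)
  expect_identical(modality(v2), "CT")
  # a second series dropped into the same directory must be rejected
  v3 <- imageVolume(array(0L + 7L, c(4, 4, 2)), spacing = c(1, 1, 1))
  writeDicomSeries(v3, file.path(td, "other"))
  file.copy(list.files(file.path(td, "other"), full.names = TRUE)[1],
            file.path(dd, "extra_0001.dcm"))
  expect_error(readVolume(dd), "SeriesInstanceUID")
})

test_that("missing files and bad formats are rejected with clear errors", {
  expect_error(readVolume(tempfile(fileext = ".nii")), "no such file")
  expect_error(readVolume(tempfile(), format = "nifti"), "no such file")
})

test_that("fillSliceGaps replicates the nearest acquired slice", {
  # 8 slices of 3 mm + 0.3 mm gap: centres span 7 * 3.3 = 23.1 mm
  v <- imageVolume(array(rep(1:8, each = 4), c(2, 2, 8)),
                   spacing = c(1, 1, 3.3), modality = "MR")
  out <- fillSliceGaps(v, sliceGeometry(3, 0.3, sliceAxis = 3),
                       targetSpacing = 0.25)
  nOut <- dim(voxels(out))[3]
  expect_equal(nOut, 93L)   # floor(23.1 / 0.25) + 1
  # independent slice-centre oracle (tie resolves to the lower index)
  pos <- (seq_len(nOut) - 1) * 0.25
  oracle <- vapply(pos, function(z) {
    d <- round(abs(z - (0:7) * 3.3), 9)
    which(d == min(d))[1]
  }, 0L)
  expect_identical(as.integer(voxels(out)[1, 1, ]), as.integer(oracle))
  # every output slice equals some input slice exactly; monotone order
  expect_true(all(voxels(out)[1, 1, ] %in% 1:8))
  expect_false(is.unsorted(voxels(out)[1, 1, ]))
  # gap 0 and target = thickness: identity
  v2 <- imageVolume(array(rnorm(32), c(2, 2, 8)), spacing = c(1, 1, 3),
                    modality = "MR")
  out2 <- fillSliceGaps(v2, sliceGeometry(3, 0, sliceAxis = 3),
                        targetSpacing = 3)
  expect_identical(voxels(out2), voxels(v2))
  # inconsistent geometry rejected
  expect_error(fillSliceGaps(v, sliceGeometry(2, 0.3, sliceAxis = 3)),
               "inconsistent")
})

test_that("resampleToGrid honours geometry, interpolation and bounds", {
  set.seed(5)
  v <- imageVolume(array(rnorm(6^3), c(6, 6, 6)), spacing = c(1, 1, 1))
  # identity, reference = moving
  out <- resampleToGrid(v, v)
  expect_equal(voxels(out), voxels(v))
  # one-voxel-pitch translation with nearest: integer shift
  tr <- similarityTransform(translation = c(1, 0, 0))
  sh <- resampleToGrid(v, v, tr, interpolation = "nearest")
  expect_equal(voxels(sh)[1:5, , ], voxels(v)[2:6, , ])
  expect_true(all(is.na(voxels(sh)[6, , ])))
  # constant volume stays constant under any in-bounds transform
  cst <- imageVolume(array(3, c(6, 6, 6)), spacing = c(1, 1, 1))
  rs <- resampleToGrid(cst, cst, similarityTransform(rotation = c(5, 3, -4),
                                                     center = c(2.5, 2.5, 2.5)))
  expect_lt(max(abs(voxels(rs)[!is.na(voxels(rs))] - 3)), 1e-12)
  # linear interpolation never exceeds the moving volume's range
  rs2 <- resampleToGrid(v, v, similarityTransform(rotation = c(10, -7, 3),
                                                  translation = c(0.3, -0.2, 0.4),
                                                  center = c(2.5, 2.5, 2.5)))
  vals <- voxels(rs2)[!is.na(voxels(rs2))]
  expect_gte(min(vals), min(voxels(v)))
  expect_lte(max(vals), max(voxels(v)))
  expect_error(resampleToGrid(v, v, similarityTransform(scale = 1e-15)),
               "degenerate")
})

test_that("volume and mask validity invariants are enforced", {
  expect_error(imageVolume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(imageVolume(array(Inf, c(2, 2, 2))), "finite")
  bad <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3)
  expect_error(imageVolume(array(0, c(2, 2, 2)), direction = bad),
               "determinant")
  g <- imageVolume(array(0, c(2, 2, 2)))
  expect_error(labelMask(array(2, c(2, 2, 2)), g), NA)  # coerced to 0/1
  expect_error(new("LabelMask", voxels = array(2L, c(2, 2, 2)),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3), label = "bone",
                   provenance = "manual"),
               "strictly 0 or 1")
})
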