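# Dice index, surface distances, model comparison, descriptive statistics.

test_that("diceIndex matches the overlap formula exactly", {
  g <- imageVolume(array(0, c(4, 4, 4)))
  a <- array(0, c(4, 4, 4)); a[1:2, 1:4, 1:4] <- 1   # 32 voxels
  b <- array(0, c(4, 4, 4)); b[2:3, 1:4, 1:4] <- 1   # 32 voxels, overlap 16
  ma <- labelMask(a, g); mb <- labelMask(b, g)
  expect_identical(diceIndex(ma, ma), 1)
  expect_identical(diceIndex(ma, mb), 0.5)
  expect_identical(diceIndex(ma, mb), diceIndex(mb, ma))
  dis <- labelMask(array(0, c(4, 4, 4)), g); dis@voxels[4, 4, 4] <- 1L
  expect_identical(diceIndex(ma, dis), 0)
  empty <- labelMask(array(0, c(4, 4, 4)), g)
  expect_identical(diceIndex(empty, empty), 1)   # degenerate convention
  # strictly monotone in overlap at fixed volumes
  overlaps <- vapply(0:4, function(k) {
    bb <- array(0, c(4, 4, 4))
    bb[1:2, 1:4, 1:4] <- 1
    if (k > 0) { bb[1, 1, 1:k] <- 0; bb[4, 4, 1:k] <- 1 }
    diceIndex(ma, labelMask(bb, g))
  }, 0)
  expect_true(all(diff(overlaps) < 0))
  g2 <- imageVolume(array(0, c(4, 4, 4)), origin = c(1, 0, 0))
  expect_error(diceIndex(ma, labelMask(b, g2)), "grid")
})

test_that("surface distances: identity, plate offset, and RMSD <= MD", {
  ball <- maskToMesh(ballMask(1.5, spacing = 0.25))
  expect_equal(unname(surfaceDistance(ball, ball)), c(0, 0))
  # two thin plates offset 0.5 mm along their normal: MD = 0.5 exactly
  mkPlate <- function(zoff) {
    g <- imageVolume(array(0, c(8, 8, 8)), spacing = rep(0.5, 3),
                     origin = c(0, 0, zoff))
    vv <- array(0, c(8, 8, 8)); vv[3:6, 3:6, 3:4] <- 1
    maskToMesh(labelMask(vv, g))
  }
  d <- surfaceDistance(mkPlate(0), mkPlate(0.5))
  expect_lt(abs(d["md"] - 0.5), 1e-6)
  expect_lte(d["rmsd"], d["md"])
  # inflating one model strictly increases both RMSD and MD
  small <- maskToMesh(ballMask(1.5, spacing = 0.25))
  prev <- c(rmsd = 0, md = 0)
  for (r in c(1.75, 2, 2.25)) {
    cur <- surfaceDistance(small, maskToMesh(ballMask(r, spacing = 0.25)))
    expect_gt(cur["rmsd"], prev["rmsd"])
    expect_gt(cur["md"], prev["md"])
    prev <- cur
  }
})

test_that("accelerated nearest-triangle search equals brute force", {
  # meshes of ~100-200 vertices, exhaustive point-to-triangle oracle
  set.seed(31)
  g <- imageVolume(array(0, c(6, 6, 6)), spacing = rep(0.5, 3))
  for (i in 1:5) {
    va <- array(runif(216) < 0.25, c(6, 6, 6)); va[3, 3, 3] <- TRUE
    vb <- array(runif(216) < 0.25, c(6, 6, 6)); vb[4, 4, 4] <- TRUE
    ma <- maskToMesh(labelMask(va, g))
    mb <- maskToMesh(labelMask(vb, g))
    dg <- surfaceDistance(ma, mb, method = "grid")
    db <- surfaceDistance(ma, mb, method = "brute")
    expect_lt(max(abs(dg - db)), 1e-12)
  }
})

test_that("surface distances are rigid-motion invariant", {
  ball <- ballMask(1.5, spacing = 0.25)
  ball2 <- perturbMask(ball, 0.2, seed = 5)
  ma <- maskToMesh(ball); mb <- maskToMesh(ball2)
  d0 <- surfaceDistance(ma, mb)
  tr <- similarityTransform(rotation = c(20, -10, 35),
                            translation = c(5, -3, 11), center = c(1, 2, 3))
  move <- function(m) new("SurfaceMesh",
                          vertices = applyTransform(tr, vertices(m)),
                          triangles = triangles(m), label = structureLabel(m))
  d1 <- surfaceDistance(move(ma), move(mb))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("RMSD <= MD holds across random perturbation pairs", {
  base <- ballMask(2, spacing = 0.5)
  for (s in 1:20) {
    a <- perturbMask(base, 0.3, seed = s)
    b <- perturbMask(base, 0.3, seed = 1000 + s)
    d <- surfaceDistance(maskToMesh(a), maskToMesh(b))
    expect_lte(d["rmsd"], d["md"] + 1e-12)
  }
})

test_that("voxelization inverts meshing for solid blobs", {
  for (r in c(1, 1.5, 2)) {
    mask <- ballMask(r, spacing = 0.25)
    mesh <- maskToMesh(mask)
    back <- voxelizeMesh(mesh, mask)
    expect_identical(voxels(back), voxels(mask))
  }
  # open meshes are rejected with the count of boundary edges
  mesh <- maskToMesh(ballMask(1, spacing = 0.25))
  open <- new("SurfaceMesh", vertices = vertices(mesh),
              triangles = triangles(mesh)[-1, , drop = FALSE],
              label = "condyle")
  expect_error(voxelizeMesh(open, ballMask(1, spacing = 0.25)),
               "not watertight")
})

test_that("compareModels populates a consistent report", {
  mask <- ballMask(1.5, spacing = 0.25)
  same <- compareModels(mask, mask)
  expect_equal(same@dsi, 1)
  expect_equal(same@rmsd, 0)
  expect_equal(same@md, 0)
  expect_equal(same@overlap, same@volumeA)
  pert <- perturbMask(mask, 0.3, seed = 9)
  rep2 <- compareModels(mask, pert)
  expect_lt(rep2@dsi, 1)
  expect_lte(rep2@rmsd, rep2@md)
  expect_lt(abs(rep2@dsi - 2 * rep2@overlap / (rep2@volumeA + rep2@volumeB)),
            1e-12)
  # a mesh/mask mix works and matches the mask/mask result
  rep3 <- compareModels(maskToMesh(mask), pert)
  expect_equal(rep3@dsi, rep2@dsi)
  expect_equal(rep3@rmsd, rep2@rmsd)
  other <- ballMask(1, spacing = 0.25, label = "disc")
  expect_error(compareModels(mask, other), "different structures")
})

test_that("descriptiveStats reports mean and sample SD with both roundings", {
  s <- descriptiveStats(c(1, 2, 3))
  expect_equal(s@mean, 2)
  expect_equal(s@sd, 1)
  s1 <- descriptiveStats(5, precision = 1L)
  expect_equal(s1@mean, 5)
  expect_equal(s1@sd, 0)
  expect_equal(s1@n, 1L)
  # published condyle DSI column: mean 0.98 at 2 decimals
  dsi <- c(0.97, 0.94, 0.99, 0.99, 1, 1, 0.93, 1, 0.98, 1)
  expect_equal(descriptiveStats(dsi, 2L)@meanRounded, 0.98)
  # the two rounding modes differ where the software truncates
  expect_equal(descriptiveStats(0.806, 2L, "half-up")@meanRounded, 0.81)
  expect_equal(descriptiveStats(0.806, 2L, "truncate")@meanRounded, 0.80)
  expect_error(descriptiveStats(numeric(0)), "no values")
})
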