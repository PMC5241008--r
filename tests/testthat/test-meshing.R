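# Mask-to-mesh extraction and STL I/O.

test_that("a single voxel meshes to a closed surface with Euler number 2", {
  g <- imageVolume(array(0, c(3, 3, 3)))
  vox <- array(0, c(3, 3, 3)); vox[2, 2, 2] <- 1
  mesh <- maskToMesh(labelMask(vox, g, label = "condyle"))
  expect_equal(meshEuler(mesh), 2)
  expect_true(isWatertight(mesh))
  expect_gt(meshVolume(mesh), 0)   # outward winding
  # no degenerate triangles
  v <- vertices(mesh); tr <- triangles(mesh)
  areas <- vapply(seq_len(nrow(tr)), function(t) {
    ab <- v[tr[t, 2], ] - v[tr[t, 1], ]
    ac <- v[tr[t, 3], ] - v[tr[t, 1], ]
    sqrt(sum(c(ab[2] * ac[3] - ab[3] * ac[2],
               ab[3] * ac[1] - ab[1] * ac[3],
               ab[1] * ac[2] - ab[2] * ac[1])^2)) / 2
  }, 0)
  expect_gt(min(areas), 1e-9)
  expect_error(maskToMesh(labelMask(array(0, c(3, 3, 3)), g)), "empty")
})

test_that("a 2 mm digital ball meshes to the analytic volume within 5%", {
  mask <- ballMask(2, spacing = 0.25)
  mesh <- maskToMesh(mask)
  expect_true(isWatertight(mesh))
  analytic <- 4 / 3 * pi * 2^3
  expect_lt(abs(meshVolume(mesh) - analytic) / analytic, 0.05)
  # repeated extraction is bit-identical
  mesh2 <- maskToMesh(mask)
  expect_identical(vertices(mesh), vertices(mesh2))
  expect_identical(triangles(mesh), triangles(mesh2))
})

test_that("mesh vertices follow the mask's world geometry", {
  vox <- array(0, c(5, 5, 5)); vox[2:4, 2:4, 2:4] <- 1
  g1 <- imageVolume(array(0, c(5, 5, 5)), spacing = c(0.5, 0.5, 0.5))
  g2 <- imageVolume(array(0, c(5, 5, 5)), spacing = c(0.5, 0.5, 0.5),
                    origin = c(3, -2, 1))
  m1 <- maskToMesh(labelMask(vox, g1))
  m2 <- maskToMesh(labelMask(vox, g2))
  expect_equal(vertices(m2),
               sweep(vertices(m1), 2, c(3, -2, 1), `+`))
  # enclosed volume tracks voxel volume for blobs
  expect_lt(abs(meshVolume(m1) - 27 * 0.125) / (27 * 0.125), 0.35)
})

test_that("binary STL round-trips and has the documented layout", {
  td <- withr::local_tempdir()
  tri <- new("SurfaceMesh",
             vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3,
                               byrow = TRUE),
             triangles = matrix(c(1L, 2L, 3L), 1, 3), label = "disc")
  p <- file.path(td, "one.stl")
  writeSTL(tri, p, sidecar = FALSE)
  expect_equal(file.info(p)$size, 134)   # 80 + 4 + 50
  back <- readSTL(p, label = "disc")
  expect_equal(nrow(triangles(back)), 1)
  expect_equal(vertices(back), vertices(tri), tolerance = 1e-7)
  # voxel-mesh round trip preserves the triangle count; sidecar carries label
  g <- imageVolume(array(0, c(3, 3, 3)))
  vox <- array(0, c(3, 3, 3)); vox[2, 2, 2] <- 1
  mesh <- maskToMesh(labelMask(vox, g, label = "condyle"))
  p2 <- file.path(td, "vox.stl")
  writeSTL(mesh, p2)
  back2 <- readSTL(p2)
  expect_equal(nrow(triangles(back2)), nrow(triangles(mesh)))
  expect_identical(structureLabel(back2), "condyle")
  expect_lt(abs(meshVolume(back2) - meshVolume(mesh)), 1e-5)
  # truncated file rejected
  raw <- readBin(p2, "raw", file.info(p2)$size)
  writeBin(raw[1:100], file.path(td, "trunc.stl"))
  expect_error(readSTL(file.path(td, "trunc.stl")), "corrupt|truncated")
})

test_that("ASCII STL is sniffed and parses to the same mesh", {
  td <- withr::local_tempdir()
  g <- imageVolume(array(0, c(3, 3, 3)))
  vox <- array(0, c(3, 3, 3)); vox[2, 2, 2] <- 1
  mesh <- maskToMesh(labelMask(vox, g, label = "disc"))
  v <- vertices(mesh); tr <- triangles(mesh)
  lines <- c("solid voxel")
  for (t in seq_len(nrow(tr))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %.9g %.9g %.9g",
                       v[tr[t, 1:3], 1], v[tr[t, 1:3], 2], v[tr[t, 1:3], 3]),
               "  endloop", " endfacet")
  }
  lines <- c(lines, "endsolid voxel")
  p <- file.path(td, "ascii.stl")
  writeLines(lines, p)
  back <- readSTL(p, label = "disc")
  expect_equal(nrow(triangles(back)), nrow(tr))
  expect_equal(meshVolume(back), meshVolume(mesh), tolerance = 1e-9)
})
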