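# Shared fixtures, built lazily and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# the default-resolution phantom (0.25 mm CT, 3.3 mm MR slice pitch)
defaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- generatePhantom(phantomSpec())
  .fixtures$phantom
}

# a coarser, faster phantom for unit-level registration checks
smallPhantom <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantom(
      phantomSpec(ctSpacing = 0.5, ctDim = c(56L, 56L, 36L),
                  mrDim = c(8L, 48L, 48L), ...))
  .fixtures[[key]]
}

# a digital ball mask: radius mm at the given spacing, centred on the grid
ballMask <- function(radius, spacing = 0.25, margin = 4L, label = "condyle") {
  n <- 2L * ceiling(radius / spacing) + 2L * margin + 1L
  half <- (n - 1) / 2
  g <- imageVolume(array(0, c(n, n, n)), spacing = rep(spacing, 3),
                   origin = rep(-half * spacing, 3))
  ax <- (seq_len(n) - 1 - half) * spacing
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  labelMask(d2 <= radius^2, g, label = label)
}

# Euler characteristic V - E + F of a triangle mesh
meshEuler <- function(mesh) {
  tr <- triangles(mesh)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(vertices(mesh)) - nrow(e) + nrow(tr)
}

# random similarity transform with bounded magnitude
randomTransform <- function(maxRot = 10, maxTrans = 5) {
  similarityTransform(rotation = runif(3, -maxRot, maxRot),
                      translation = runif(3, -maxTrans, maxTrans),
                      center = runif(3, -5, 5))
}
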