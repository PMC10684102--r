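test_that("disk smoothing preserves constants and is the identity below vertex spacing", {
  mesh <- testMesh()
  const <- rep(3.7, nVertices(mesh))
  expect_equal(diskSmooth(const, mesh, 10), const, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(nVertices(mesh))
  expect_equal(diskSmooth(x, mesh, 1e-6), x, tolerance = 1e-12)
})

test_that("disk smoothing excludes invalid vertices and reduces short-range roughness", {
  mesh <- testMesh()
  v <- nVertices(mesh)
  set.seed(2)
  x <- rnorm(v)
  x[5] <- NA
  sm <- diskSmooth(x, mesh, 8)
  expect_true(is.na(sm[5]))
  ## manual disk mean around vertex 1, excluding the invalid vertex
  cc <- companionCoords(mesh, "inflated")
  d <- sqrt(colSums((t(cc) - cc[1, ])^2))
  disk <- which(d <= 8 & !is.na(x))
  expect_equal(sm[1], mean(x[disk]), tolerance = 1e-12)
  ## smoothing shrinks the mean squared difference across mesh edges
  ## (vertex spacing on this mesh is ~14 mm, so use a larger disk)
  e <- meshEdges(mesh)
  y <- rnorm(v)
  sy <- diskSmooth(y, mesh, 25)
  rough <- function(z) mean((z[e[, 1]] - z[e[, 2]])^2)
  expect_lt(rough(sy), 0.5 * rough(y))
})

test_that("disk smoothing requires inflated coordinates", {
  mesh <- testMesh()
  bare <- new("SurfaceMesh", vertices = meshVertices(mesh),
              triangles = meshTriangles(mesh), companions = list())
  expect_error(diskSmooth(rep(1, nVertices(mesh)), bare, 10), "inflated")
})

test_that("discrete mean curvature matches 1/R on spheres", {
  h1 <- meanCurvature(makeIcosphere(4, 1))
  expect_true(all(abs(h1 - 1) <= 0.02))
  h2 <- meanCurvature(makeIcosphere(4, 2))
  expect_true(all(abs(h2 - 0.5) <= 0.01))
})

test_that("curvature sign follows triangle orientation and degenerate faces error", {
  mesh <- makeIcosphere(3, 1)
  flipped <- new("SurfaceMesh", vertices = meshVertices(mesh),
                 triangles = meshTriangles(mesh)[, c(1, 3, 2)],
                 companions = mesh@companions)
  expect_equal(meanCurvature(flipped), -meanCurvature(mesh), tolerance = 1e-10)
  bad <- meshVertices(mesh)
  tri <- meshTriangles(mesh)
  bad[tri[1, 2], ] <- bad[tri[1, 1], ]   # collapse one edge of triangle 1
  degenerate <- new("SurfaceMesh", vertices = bad, triangles = tri,
                    companions = mesh@companions)
  expect_error(meanCurvature(degenerate), "degenerate")
})

test_that("parcel centroids are exact Euclidean medoids", {
  ## single-vertex parcel and collinear triple on a hand-built mesh
  vv <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(5, 5, 5))
  mesh <- new("SurfaceMesh", vertices = vv,
              triangles = matrix(c(1L, 2L, 4L), 1), companions = list())
  labels <- c(1L, 1L, 1L, 2L)
  cv <- parcelCentroids(mesh, labels)
  expect_identical(cv[1], 2L)   # middle of three collinear vertices
  expect_identical(cv[2], 4L)   # singleton parcel
  ## random 20-vertex parcel vs exhaustive O(n^2) search
  mesh3 <- testMesh()
  set.seed(3)
  members <- sample(nVertices(mesh3), 20)
  labels3 <- integer(nVertices(mesh3))
  labels3[members] <- 1L
  got <- parcelCentroids(mesh3, labels3)[1]
  coords <- meshVertices(mesh3)[members, ]
  sums <- sapply(seq_len(20), function(i)
    sum(sqrt(colSums((t(coords) - coords[i, ])^2))))
  expect_identical(got, members[which.min(sums)])
  emptyFirst <- labels3
  emptyFirst[members] <- 2L   # parcel 1 has no vertices
  expect_error(parcelCentroids(mesh3, emptyFirst), "parcel 1 is empty")
  expect_error(parcelCentroids(mesh3, integer(nVertices(mesh3))), "no parcels")
})

test_that("geodesic distances are metric-like and rotation invariant", {
  mesh <- testMesh()
  parc <- testParc()
  d <- geodesicParcelDistance(mesh, parc)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, nParcels(parc)), ignore_attr = TRUE)
  ## triangle inequality over sampled triples
  set.seed(4)
  for (rep in 1:200) {
    ijk <- sample(nParcels(parc), 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-9)
  }
  ## rigid rotation leaves distances unchanged
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
  rmesh <- new("SurfaceMesh", vertices = meshVertices(mesh) %*% t(rot),
               triangles = meshTriangles(mesh), companions = mesh@companions)
  expect_equal(geodesicParcelDistance(rmesh, centroidVertices(parc)),
               d, tolerance = 1e-9)
})

test_that("adjacent centroids connected by a mesh edge are one edge apart", {
  mesh <- testMesh()
  e <- meshEdges(mesh)[1, ]
  d <- geodesicParcelDistance(mesh, e)
  len <- sqrt(sum((meshVertices(mesh)[e[1], ] - meshVertices(mesh)[e[2], ])^2))
  expect_equal(d[1, 2], len, tolerance = 1e-12)
})

test_that("graph geodesics track great-circle distances on the sphere", {
  mesh <- testMesh4()
  parc <- fixture("parc4.40", makeParcellation(mesh, 40, seed = 2))
  d <- geodesicParcelDistance(mesh, parc)
  u <- companionCoords(mesh, "sphere")[centroidVertices(parc), ]
  ana <- 100 * acos(pmin(1, pmax(-1, tcrossprod(u))))
  rel <- abs(d - ana) / pmax(ana, 1)
  expect_lt(max(rel[ana > 1]), 0.05)
})

test_that("parcellation aggregation uses the column-wise median of valid vertices", {
  labels <- c(1L, 1L, 1L, 2L, 0L)
  x <- c(1, 2, 100, 7, 99)
  out <- parcellate(x, labels)
  expect_equal(out[, 1], c(`1` = 2, `2` = 7))
  ## permutation invariance within a parcel
  perm <- c(3L, 1L, 2L, 4L, 5L)
  expect_equal(parcellate(x[perm], labels[perm]), out)
  ## constant map, multi-column, and NA handling
  m <- cbind(a = rep(5, 5), b = c(1, NA, 3, 4, 5))
  outm <- parcellate(m, labels, aggregator = "mean")
  expect_equal(outm["1", "a"], 5)
  expect_equal(outm["1", "b"], 2)
  expect_error(parcellate(x[1:3], labels), "length")
})

test_that("region exclusion clears the inclusion mask and validates labels", {
  parc <- testParc()
  types <- rep(c("agranular", "eulaminate2"), each = 20)
  out <- excludeRegions(parc, types)
  expect_identical(length(includedParcels(out)), 20L)
  expect_identical(includedParcels(out), 21:40)
  ## no excluded types present: mask unchanged
  out2 <- excludeRegions(parc, rep("koniocortex", 40))
  expect_identical(includedParcels(out2), includedParcels(parc))
  expect_error(excludeRegions(parc, rep("mystery", 40)), "unknown")
  expect_error(excludeRegions(parc, rep("agranular", 40)), "no included")
})
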