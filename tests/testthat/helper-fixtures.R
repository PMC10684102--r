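## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

## subdivision-3 icosphere (642 vertices) with a 40-parcel parcellation
testMesh <- function() fixture("mesh3", makeIcosphere(3, 100))
testParc <- function() fixture("parc3", makeParcellation(testMesh(), 40, seed = 7))

## subdivision-4 icosphere (2562 vertices)
testMesh4 <- function() fixture("mesh4", makeIcosphere(4, 100))

## small full simulation: 60 parcels on the subdivision-3 sphere
testConfig <- function() simulationConfig(seed = 5, nParcels = 60,
                                          meshSubdivisions = 3)
testSim <- function() fixture("sim3", simulateCortex(testConfig()))

## random relative-thickness profile table (rows sum to 1)
randomProfiles <- function(p, k = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(p * k, 0.5, 1.5), p, k)
  m / rowSums(m)
}

## independent residual-regression oracle for the partial correlation:
## correlate the least-squares residuals of x on z and y on z
residualPartialCor <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

## parcel centroid coordinates on the unit sphere
sphereCentroids <- function(mesh, parc) {
  companionCoords(mesh, "sphere")[centroidVertices(parc), , drop = FALSE]
}

## decile-binned empirical variogram restricted to the fitted range
## (pair distances up to the median), as a closure over a distance matrix
binnedVariogram <- function(gd) {
  p <- nrow(gd)
  idx <- ltcov:::.lowerPairs(p)
  dv <- gd[idx]
  near <- dv <= stats::median(dv)
  idx <- idx[near, , drop = FALSE]
  bins <- cut(dv[near], stats::quantile(dv[near], 0:8 / 8),
              include.lowest = TRUE)
  function(z) as.vector(tapply(0.5 * (z[idx[, 1]] - z[idx[, 2]])^2, bins, mean))
}
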