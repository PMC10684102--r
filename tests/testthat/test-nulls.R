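test_that("spin assignment is the identity for the identity rotation", {
  mesh <- testMesh()
  parc <- testParc()
  cc <- sphereCentroids(mesh, parc)
  expect_identical(ltcov:::.spinAssign(cc, diag(3)), seq_len(40))
  expect_identical(ltcov:::.spinAssign(cc, diag(3), bijective = TRUE),
                   seq_len(40))
})

test_that("spin permutations are valid assignments on the sphere", {
  mesh <- testMesh()
  parc <- testParc()
  cc <- sphereCentroids(mesh, parc)
  perms <- spinPermutation(cc, nPerm = 20, seed = 3)
  expect_identical(dim(perms), c(20L, 40L))
  expect_true(all(perms >= 1 & perms <= 40))
  ## bijective variant visits every parcel exactly once
  bij <- spinPermutation(cc, nPerm = 5, seed = 3, bijective = TRUE)
  for (k in 1:5) expect_identical(sort(bij[k, ]), 1:40)
  ## determinism and the off-sphere error
  expect_identical(perms, spinPermutation(cc, nPerm = 20, seed = 3))
  bad <- cc
  bad[1, ] <- bad[1, ] * 2
  expect_error(spinPermutation(bad, nPerm = 5, seed = 1), "sphere")
})

test_that("spun maps preserve spatial autocorrelation where shuffles destroy it", {
  mesh <- testMesh()
  parc <- fixture("parc3.100", makeParcellation(testMesh(), 100, seed = 1))
  cc <- sphereCentroids(mesh, parc)
  gd <- fixture("gd3.100", geodesicParcelDistance(mesh, parc))
  ## a smooth map: exponential-kernel correlated field
  set.seed(4)
  k <- exp(-gd / 60) + diag(1e-6, 100)
  x <- as.vector(t(chol(k)) %*% rnorm(100))
  vg <- binnedVariogram(gd)
  vgX <- vg(x)
  perms <- spinPermutation(cc, nPerm = 100, seed = 5)
  sseSpin <- mean(sapply(1:100, function(i) sum((vg(x[perms[i, ]]) - vgX)^2)))
  set.seed(6)
  sseShuffle <- mean(replicate(100, sum((vg(sample(x)) - vgX)^2)))
  expect_lt(sseSpin, 0.5 * sseShuffle)
})

test_that("variogram surrogates match the original's variogram, not its values", {
  mesh <- testMesh()
  parc <- fixture("parc3.100", makeParcellation(testMesh(), 100, seed = 1))
  gd <- fixture("gd3.100", geodesicParcelDistance(mesh, parc))
  set.seed(7)
  k <- exp(-gd / 60) + diag(1e-6, 100)
  x <- as.vector(t(chol(k)) %*% rnorm(100))
  ens <- variogramSurrogates(x, gd, nPerm = 100, seed = 8)
  sur <- values(ens)
  expect_identical(dim(sur), c(100L, 100L))
  ## variogram fidelity (within the fitted range, up to the median pairwise
  ## distance): surrogate SSE well below naive-shuffle SSE
  vg <- binnedVariogram(gd)
  vgX <- vg(x)
  sseSur <- mean(apply(sur, 1, function(z) sum((vg(z) - vgX)^2)))
  set.seed(9)
  sseShuf <- mean(replicate(100, sum((vg(sample(x)) - vgX)^2)))
  expect_lt(sseSur, 0.5 * sseShuf)
  ## surrogates of a short-correlation-length map are uncorrelated with it
  set.seed(17)
  kS <- exp(-gd / 25) + diag(1e-6, 100)
  xS <- as.vector(t(chol(kS)) %*% rnorm(100))
  ensS <- variogramSurrogates(xS, gd, nPerm = 100, seed = 18)
  expect_lt(mean(abs(apply(values(ensS), 1, cor, y = xS))), 0.15)
  ## determinism
  ens2 <- variogramSurrogates(x, gd, nPerm = 100, seed = 8)
  expect_identical(sur, values(ens2))
})

test_that("a constant map yields (near-)constant surrogates with beta ~ 0", {
  mesh <- testMesh()
  parc <- fixture("parc3.100", makeParcellation(testMesh(), 100, seed = 1))
  gd <- fixture("gd3.100", geodesicParcelDistance(mesh, parc))
  ens <- variogramSurrogates(rep(2.5, 100), gd, nPerm = 10, seed = 1)
  expect_lt(max(abs(ens@diagnostics$beta)), 1e-20)
  expect_lt(max(apply(values(ens), 1, sd)), 1e-10)
  expect_error(variogramSurrogates(rnorm(100), gd * 0, nPerm = 5, seed = 1),
               "degenerate")
  expect_error(variogramSurrogates(rnorm(10), gd[1:10, 1:10], nPerm = 5,
                                   seed = 1), "30")
})

test_that("correlation tests return exact p for self-correlation and honor the +1 rule", {
  mesh <- testMesh()
  parc <- testParc()
  cc <- sphereCentroids(mesh, parc)
  set.seed(10)
  x <- rnorm(40)
  out <- correlationTest(x, x, nullSource = "spin", nPerm = 99, seed = 2,
                         sphereCoords = cc)
  expect_equal(observedStat(out), 1)
  expect_equal(pValue(out), 1 / 100)
  expect_identical(out@nPerm, 99L)
  expect_gt(min(nullStats(out)), -1)
})

test_that("matrix correlation excludes undefined edges exactly as hand-computed", {
  a <- matrix(NA_real_, 4, 4)
  b <- matrix(NA_real_, 4, 4)
  av <- c(0.1, 0.5, -0.2, 0.8, 0.3, 0.7)
  bv <- c(0.2, 0.4, -0.1, 0.9, 0.1, 0.6)
  idx <- ltcov:::.lowerPairs(4)
  a[idx] <- av; a[idx[, c(2, 1)]] <- av
  b[idx] <- bv; b[idx[, c(2, 1)]] <- bv
  a[3, 2] <- a[2, 3] <- NA   # one undefined edge in a
  mesh <- testMesh()
  cc <- companionCoords(mesh, "sphere")[c(1, 50, 200, 400), ]
  out <- correlationTest(a, b, nullSource = "spin", nPerm = 19, seed = 1,
                         sphereCoords = cc)
  keep <- c(1, 2, 3, 5, 6)   # lower-triangle order, edge (3,2) dropped
  expect_equal(observedStat(out), cor(av[keep], bv[keep]), tolerance = 1e-12)
  ## variogram nulls are defined for maps only
  expect_error(correlationTest(a, b, nullSource = "variogram", nPerm = 5,
                               seed = 1, dist = matrix(1, 4, 4)), "spin")
})

test_that("spin conjugation of a symmetric matrix stays symmetric", {
  prof <- randomProfiles(40, seed = 11)
  m <- values(buildLTC(prof))
  perms <- spinPermutation(sphereCentroids(testMesh(), testParc()),
                           nPerm = 5, seed = 4)
  for (k in 1:5) {
    mk <- m[perms[k, ], perms[k, ]]
    expect_equal(mk, t(mk))
  }
})

test_that("the spin ANOVA matches the F formula and counts its post hocs", {
  mesh <- testMesh()
  parc <- testParc()
  cc <- sphereCentroids(mesh, parc)
  set.seed(12)
  x <- rnorm(40)
  g <- rep(c("a", "b", "c", "d"), each = 10)
  out <- anovaSpin(x, g, nPerm = 49, seed = 3, sphereCoords = cc)
  oracle <- summary(stats::aov(x ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(out$F, oracle, tolerance = 1e-10)
  expect_identical(nrow(out$postHoc), 6L)
  expect_true(all(out$postHoc$pBonferroni >= out$postHoc$pSpin))
  expect_true(all(out$postHoc$pBonferroni <=
                  pmin(1, out$postHoc$pSpin * choose(4, 2))))
  ## zero within-group variance: F is infinite and beats every null
  xDeg <- rep(c(1, 2, 3, 4), each = 10)
  outDeg <- anovaSpin(xDeg, g, nPerm = 49, seed = 3, sphereCoords = cc)
  expect_identical(outDeg$pSpin, 1 / 50)
  ## small groups are dropped with a warning
  gSmall <- g
  gSmall[1:10] <- c("tiny", rep("b", 9))
  expect_warning(anovaSpin(x, gSmall, nPerm = 9, seed = 1, sphereCoords = cc),
                 "tiny")
})

test_that("within/between-type covariance differences match hand computations", {
  ## 4 parcels, 2 types; 6 edges
  m <- matrix(NA_real_, 4, 4)
  idx <- ltcov:::.lowerPairs(4)
  ev <- c(0.9, 0.1, 0.2, 0.3, 0.0, 0.8)  # edges 21,31,41,32,42,43
  m[idx] <- ev; m[idx[, c(2, 1)]] <- ev
  types <- c("s", "s", "t", "t")
  mesh <- testMesh()
  cc <- companionCoords(mesh, "sphere")[c(1, 50, 200, 400), ]
  out <- withinBetweenTypeTest(m, types, nPerm = 19, seed = 1,
                               sphereCoords = cc)
  ## type s: within = edge(2,1); between = edges (3,1),(4,1),(3,2),(4,2)
  expect_equal(out$perType$delta[out$perType$type == "s"],
               0.9 - mean(c(0.1, 0.2, 0.3, 0.0)))
  expect_equal(out$perType$delta[out$perType$type == "t"],
               0.8 - mean(c(0.1, 0.2, 0.3, 0.0)))
  expect_equal(observedStat(out$overall),
               mean(c(0.9, 0.8)) - mean(c(0.1, 0.2, 0.3, 0.0)))
})

test_that("planted within-type blocks are detected against the spin null", {
  mesh <- testMesh()
  parc <- fixture("parc3.100", makeParcellation(testMesh(), 100, seed = 1))
  cc <- sphereCentroids(mesh, parc)
  set.seed(13)
  types <- sample(rep(c("u", "v"), 50))   # spatially interleaved types
  m <- matrix(NA_real_, 100, 100)
  idx <- ltcov:::.lowerPairs(100)
  same <- types[idx[, 1]] == types[idx[, 2]]
  vals <- ifelse(same, 1, -1) + rnorm(nrow(idx), sd = 0.05)
  m[idx] <- vals; m[idx[, c(2, 1)]] <- vals
  out <- withinBetweenTypeTest(m, types, nPerm = 99, seed = 2,
                               sphereCoords = cc)
  expect_true(all(out$perType$delta > 0))
  expect_equal(pValue(out$overall), 1 / 100)
  expect_true(all(out$perType$pSpin == 1 / 100))
})

test_that("JSD similarity hits its exact bounds and symmetry", {
  labels <- rep(1:3, each = 40)
  ## parcels 1 and 2 share a distribution; parcel 3 is disjoint
  x <- c(rep(c(0.1, 0.4), 20), rep(c(0.1, 0.4), 20), rep(c(10, 11), 20))
  sim <- jsdSimilarity(x, labels, nBins = 16)
  expect_equal(sim[1, 2], 1)
  expect_equal(sim[1, 3], 0)
  expect_equal(sim[2, 3], 0)
  expect_equal(sim, t(sim))
  expect_equal(diag(sim), rep(1, 3), ignore_attr = TRUE)
  ## parcels below the vertex minimum are undefined
  labs2 <- c(rep(1L, 3), rep(2L, 60), rep(3L, 57))
  sim2 <- jsdSimilarity(x, labs2, nBins = 16)
  expect_true(all(is.na(sim2[1, ])))
  expect_false(is.na(sim2[2, 3]))
})
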