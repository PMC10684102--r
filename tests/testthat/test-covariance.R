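test_that("relative thickness normalizes rows and propagates masks", {
  expect_equal(values(relativeThickness(matrix(1, 1, 6)))[1, ], rep(1 / 6, 6),
               ignore_attr = TRUE)
  m <- matrix(c(0.2, 0.4, 0.6, 0.2, 0.4, 0.2), 1)
  expect_equal(values(relativeThickness(m))[1, ],
               c(0.1, 0.2, 0.3, 0.1, 0.2, 0.1), ignore_attr = TRUE)
  set.seed(1)
  big <- matrix(runif(60, 0.1, 2), 10, 6)
  big[4, ] <- NA   # invalid row stays masked, not zeroed
  rel <- relativeThickness(big)
  expect_equal(rowSums(values(rel))[-4], rep(1, 9), ignore_attr = TRUE)
  expect_true(all(is.na(values(rel)[4, ])))
  zero <- big
  zero[2, ] <- 0
  expect_error(relativeThickness(zero), "row\\(s\\): 2")
})

test_that("the partial correlation equals the residual-regression oracle", {
  set.seed(42)
  for (rep in 1:25) {
    x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
    expect_equal(profilePartialCorrelation(x, y, z),
                 residualPartialCor(x, y, z), tolerance = 1e-10)
  }
  x <- rnorm(6); z <- rnorm(6)
  expect_equal(profilePartialCorrelation(x, x, z), 1, tolerance = 1e-12)
  expect_equal(profilePartialCorrelation(x, -x, z), -1, tolerance = 1e-12)
  expect_error(profilePartialCorrelation(rep(1, 6), x, z), "constant")
  expect_error(profilePartialCorrelation(x, rnorm(6), x), "collinear")
  expect_error(profilePartialCorrelation(x[1:3], rnorm(3), rnorm(3)), "4")
})

test_that("the LTC matrix matches the element-wise residual oracle", {
  prof <- randomProfiles(20, seed = 7)
  ltc <- buildLTC(prof)
  z <- colMeans(prof)
  expect_true(all(is.na(diag(values(ltc)))))
  for (i in 2:20) {
    for (j in seq_len(i - 1)) {
      expect_equal(values(ltc)[i, j],
                   atanh(residualPartialCor(prof[i, ], prof[j, ], z)),
                   tolerance = 1e-10)
    }
  }
  ## Fisher z at r = 0.5 is log(3)/2
  expect_equal(atanh(0.5), log(3) / 2, tolerance = 1e-12)
})

test_that("LTC is symmetric and consistent under parcel reordering", {
  prof <- randomProfiles(15, seed = 3)
  ltc <- values(buildLTC(prof))
  expect_lt(max(abs(ltc - t(ltc)), na.rm = TRUE), 1e-10)
  perm <- sample(15)
  permuted <- values(buildLTC(prof[perm, ]))
  expect_equal(permuted, ltc[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical profiles give the finite maximal entry; collinearity errors", {
  prof <- randomProfiles(10, seed = 5)
  prof[2, ] <- prof[1, ]
  ltc <- values(buildLTC(prof))
  expect_true(is.finite(ltc[2, 1]))
  expect_equal(ltc[2, 1], max(ltc, na.rm = TRUE))
  ## a profile exactly equal to the covariate is degenerate
  profBad <- randomProfiles(10, seed = 6)
  covar <- rnorm(6)
  profBad[3, ] <- covar
  expect_error(buildLTC(profBad, covariate = covar), "collinear")
})

test_that("alternative covariance metrics behave as documented", {
  prof <- randomProfiles(12, seed = 9)
  pe <- buildLTC(prof, metric = "pearson")
  expect_true(pe@fisherZ)
  expect_equal(values(pe)[3, 5], atanh(cor(prof[3, ], prof[5, ])),
               tolerance = 1e-12)
  eu <- buildLTC(prof, metric = "euclidean")
  expect_false(eu@fisherZ)
  expect_equal(values(eu)[3, 5], -sqrt(sum((prof[3, ] - prof[5, ])^2)),
               tolerance = 1e-12)
  ## closest pair under euclidean has the largest (least negative) value
  prof2 <- rbind(prof, prof[1, ] + 1e-4)
  eu2 <- values(buildLTC(prof2, metric = "euclidean"))
  expect_equal(which.max(eu2[13, -13]), 1L, ignore_attr = TRUE)
})

test_that("profile covariance shares the LTC machinery", {
  set.seed(8)
  prof <- matrix(rnorm(15 * 50, mean = 5), 15, 50)
  mpc <- buildProfileCovariance(prof)
  expect_identical(mpc@kind, "MPC")
  alt <- buildLTC(prof, metric = "partial", kind = "MPC")
  expect_identical(values(mpc), values(alt))
  ## profiles identical up to positive scale: equal, maximal off-diagonals
  base <- rnorm(50, mean = 5)
  scaled <- outer(c(1, 2, 3, 0.5), base)
  mpc2 <- values(buildProfileCovariance(rbind(scaled, matrix(rnorm(100), 2, 50))))
  offs <- mpc2[1:4, 1:4][lower.tri(matrix(0, 4, 4))]
  ## equal and maximal on the correlation scale (arctanh amplifies the last
  ## floating-point digits near r = 1, so compare through tanh)
  expect_equal(diff(range(tanh(offs))), 0, tolerance = 1e-12)
  expect_equal(max(tanh(mpc2), na.rm = TRUE), max(tanh(offs)), tolerance = 1e-12)
  expect_gt(min(offs), max(mpc2[5:6, ], na.rm = TRUE))
  expect_error(buildProfileCovariance(prof[, 1:5]), "10")
})

test_that("laminar intensities are recovered from piecewise-constant profiles", {
  depths <- (seq_len(200) - 0.5) / 200
  levels <- c(2, 4, 1, 6, 3, 5)
  fr <- c(0.1, 0.15, 0.25, 0.1, 0.2, 0.2)
  bounds <- cumsum(fr)
  layerOf <- findInterval(depths, c(0, bounds), rightmost.closed = TRUE)
  prof <- matrix(levels[pmin(layerOf, 6)], 1)
  out <- laminarIntensity(prof, matrix(fr, 1), samplesPerLayer = 10,
                          depthFractions = depths)
  expect_equal(out[1, ], levels, tolerance = 0.05, ignore_attr = TRUE)
  ## constant profile: every laminar intensity equals the constant
  flat <- laminarIntensity(matrix(7, 1, 200), matrix(fr, 1),
                           depthFractions = depths)
  expect_equal(flat[1, ], rep(7, 6), ignore_attr = TRUE)
  ## one sample per layer reads the midpoint
  mid <- laminarIntensity(prof, matrix(fr, 1), samplesPerLayer = 1,
                          depthFractions = depths)
  expect_equal(mid[1, ], levels, tolerance = 0.05, ignore_attr = TRUE)
  ## zero-thickness layer is masked
  fr0 <- c(0.2, 0, 0.3, 0.1, 0.2, 0.2)
  out0 <- laminarIntensity(prof, matrix(fr0, 1), depthFractions = depths)
  expect_true(is.na(out0[1, 2]))
  expect_true(all(!is.na(out0[1, -2])))
})

test_that("matrix fusion rank-aligns and concatenates", {
  prof <- randomProfiles(12, seed = 10)
  m <- buildLTC(prof)
  fused <- fuseMatrices(m, m)
  expect_identical(dim(fused), c(12L, 24L))
  expect_equal(fused[, 1:12], fused[, 13:24], ignore_attr = TRUE)
  ## both halves share the value range after rescaling
  set.seed(11)
  other <- buildLTC(randomProfiles(12, seed = 12))
  fused2 <- fuseMatrices(m, other)
  expect_equal(range(fused2[, 1:12], na.rm = TRUE),
               range(fused2[, 13:24], na.rm = TRUE), tolerance = 1e-12)
  ## the fused self-pair embeds like the original matrix (checked on
  ## profiles with a real planted axis; iid profiles have no stable G1)
  sim <- testSim()
  profS <- parcellate(relativeThickness(sim$thickness), sim$parcellation)
  mS <- buildLTC(profS)
  gM <- gradientLoadings(covarianceGradients(mS))[, 1]
  gF <- gradientLoadings(covarianceGradients(fuseMatrices(mS, mS)))[, 1]
  expect_gt(abs(cor(gM, gF)), 0.95)
  expect_error(fuseMatrices(values(m), values(m)[1:10, 1:10]), "parcel set")
})

test_that("intraregional homogeneity matches a hand calculation", {
  ## 4 vertices, 2 regions; 6 edges total
  m <- matrix(NA_real_, 4, 4)
  m[2, 1] <- m[1, 2] <- 0.8   # within A
  m[4, 3] <- m[3, 4] <- 0.4   # within B
  m[3, 1] <- m[1, 3] <- 0.1
  m[4, 1] <- m[1, 4] <- 0.2
  m[3, 2] <- m[2, 3] <- 0.3
  m[4, 2] <- m[2, 4] <- 0.0
  labs <- c("A", "A", "B", "B")
  out <- intraregionalHomogeneity(m, labs)
  expect_equal(out[["A"]], 0.8 - mean(c(0.1, 0.2, 0.3, 0.0)))
  expect_equal(out[["B"]], 0.4 - mean(c(0.1, 0.2, 0.3, 0.0)))
  ## a region of identical profiles amid noise scores strongly positive
  set.seed(13)
  prof <- randomProfiles(30, seed = 13)
  prof[1:10, ] <- matrix(prof[1, ], 10, 6, byrow = TRUE) +
    matrix(rnorm(60, sd = 1e-4), 10)
  vc <- values(buildLTC(prof))
  score <- intraregionalHomogeneity(vc, rep(c("tight", "loose", "other"),
                                            each = 10))
  expect_gt(score[["tight"]], 1)
  ## under random relabelling the scores average out to ~0
  set.seed(14)
  perms <- replicate(500, {
    s <- intraregionalHomogeneity(vc, sample(rep(c("x", "y", "z"), each = 10)))
    mean(s)
  })
  expect_lt(abs(mean(perms)), 0.1)
  ## regions with < 2 vertices are undefined
  one <- intraregionalHomogeneity(vc, c("solo", rep(c("y", "z"), c(14, 15))))
  expect_true(is.na(one[["solo"]]))
})
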