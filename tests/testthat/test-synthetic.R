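test_that("parcellations are deterministic, contiguous and cover the mesh", {
  mesh <- testMesh()
  p1 <- makeParcellation(mesh, 40, seed = 7)
  p2 <- makeParcellation(mesh, 40, seed = 7)
  expect_identical(parcelLabels(p1), parcelLabels(p2))
  expect_true(all(parcelLabels(p1) >= 1L))
  expect_identical(sort(unique(parcelLabels(p1))), 1:40)
  ## contiguity: each parcel induces one connected component on the mesh graph
  e <- meshEdges(mesh)
  lab <- parcelLabels(p1)
  for (k in 1:40) {
    members <- which(lab == k)
    sub <- e[lab[e[, 1]] == k & lab[e[, 2]] == k, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(sub, members), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(members) - igraph::vcount(g)))
    expect_equal(igraph::components(g)$no, 1)
  }
  expect_identical(unique(parcelLabels(makeParcellation(mesh, 1, seed = 1))), 1L)
  expect_error(makeParcellation(mesh, nVertices(mesh) + 1, seed = 1), "exceed")
})

test_that("noiseless laminar fields are strictly monotone along the planted axis", {
  cfg <- simulationConfig(seed = 1, noiseSd = 0, curvatureCoupling = 0)
  mesh <- testMesh()
  lam <- sampleLaminarThickness(mesh, cfg)
  rel <- values(relativeThickness(lam$thickness))
  expect_equal(cor(lam$axis, rel[, 3], method = "spearman"), 1, tolerance = 1e-5)
  expect_equal(cor(lam$axis, rowSums(rel[, 2:4]), method = "spearman"), 1,
               tolerance = 1e-5)
  expect_equal(cor(lam$axis, rowSums(rel[, 5:6]), method = "spearman"), -1,
               tolerance = 1e-5)
})

test_that("generated thickness is positive and curvature thins superficial layers", {
  mesh <- testMesh4()
  cfg <- simulationConfig(seed = 3, meshSubdivisions = 4)
  lam <- sampleLaminarThickness(mesh, cfg)
  th <- values(lam$thickness)
  expect_true(all(th > 0))
  expect_true(all(rowSums(th) > 0))
  rel <- th / rowSums(th)
  expect_lt(cor(lam$curvature, rowSums(rel[, 1:3])), 0)
  ## determinism from the config seed
  lam2 <- sampleLaminarThickness(mesh, cfg)
  expect_identical(th, values(lam2$thickness))
})

test_that("intensity profiles are piecewise constant with boundaries at cumulative fractions", {
  mesh <- testMesh()
  cfg <- testConfig()
  lam <- sampleLaminarThickness(mesh, cfg)
  ## equal levels, no drift, no noise: profile constant over depth
  flat <- sampleIntensityProfiles(mesh, lam$thickness, cfg,
                                  baseLevels = rep(1.3, 6),
                                  levelSlopes = rep(0, 6), levelNoiseSd = 0)
  expect_equal(values(flat), matrix(1.3, nVertices(mesh), 50),
               ignore_attr = TRUE)
  ## boundaries: profile changes exactly where depth bins cross the
  ## cumulative relative thickness
  prof <- sampleIntensityProfiles(mesh, lam$thickness, cfg, levelNoiseSd = 0)
  fr <- values(lam$thickness) / rowSums(values(lam$thickness))
  for (i in c(1, 100, 400)) {
    bounds <- cumsum(fr[i, ])[1:5]
    jumps <- which(diff(values(prof)[i, ]) != 0)
    binOfBound <- findInterval(bounds, seq(0, 1, length.out = 51),
                               rightmost.closed = TRUE)
    expect_true(all(jumps %in% c(binOfBound - 1L, binOfBound)))
  }
  ## layer-IV level drifts upward along the planted axis
  l4 <- laminarIntensity(prof, fr, samplesPerLayer = 3)[, 4]
  expect_gt(cor(lam$axis, l4, method = "spearman"), 0)
})

test_that("directed connectivity plants a recoverable hierarchy", {
  mesh <- testMesh()
  parc <- testParc()
  ## 2-parcel toy, no noise: the higher node sends the stronger weight
  two <- new("Parcellation", labels = ifelse(parcelLabels(parc) <= 20, 1L, 2L),
             includedMask = rep(TRUE, 2),
             centroidVertex = centroidVertices(parc)[c(1L, 21L)])
  cfg0 <- simulationConfig(seed = 2, ecNoiseSd = 0)
  res <- sampleEffectiveConnectivity(mesh, two, cfg0, hierarchy = c(1, -1))
  expect_gt(res$ec[1, 2], res$ec[2, 1])
  ## equal hierarchy, no noise: zero asymmetry everywhere
  resEq <- sampleEffectiveConnectivity(mesh, two, cfg0, hierarchy = c(1, 1))
  expect_equal(resEq$ec[1, 2], resEq$ec[2, 1], tolerance = 1e-12)
  ## asymmetry hierarchy recovers the planted scores
  cfg <- simulationConfig(seed = 2)
  resF <- sampleEffectiveConnectivity(mesh, parc, cfg)
  h <- asymmetryHierarchy(resF$ec)$hierarchy
  expect_gt(cor(h, resF$hierarchy), 0.9)
})

test_that("SC density follows the logistic intercept and FC its closed forms", {
  set.seed(9)
  n <- 20000
  ltc <- rnorm(n)
  gd <- runif(n, 5, 200)
  cfg <- simulationConfig(seed = 4, beta0 = -1, betaLtc = 0, betaGd = 0,
                          fcDecayLength = Inf, fcLtcCoupling = 0, fcNoiseSd = 0)
  out <- sampleScFc(ltc, gd, cfg)
  expect_equal(mean(out$sc), plogis(-1), tolerance = 0.01)
  expect_equal(out$fc, rep(1, n), tolerance = 1e-9)
  ## matrix form: symmetric output with NA diagonal, deterministic in seed
  sim <- testSim()
  expect_true(all(is.na(diag(sim$sc))))
  expect_equal(sim$sc, t(sim$sc))
  expect_equal(sim$fc, t(sim$fc))
  out2 <- sampleScFc(values(sim$ltcGenerative), sim$gd, sim$config)
  expect_identical(out2$sc, sim$sc)
})

test_that("cortical types fall at axis sextiles and mask a contiguous band", {
  parc <- testParc()
  axis <- seq(0, 1, length.out = 40)
  types <- assignCorticalTypes(parc, axis, seed = 1, noise = 0)
  expect_identical(as.integer(table(types)), c(6L, 7L, 7L, 6L, 7L, 7L))
  expect_identical(as.character(types[1:6]), rep("agranular", 6))
  expect_true(all(diff(as.integer(types)) >= 0))
  ## all six types present at >= 60 parcels
  parc60 <- testSim()$parcellation
  types60 <- assignCorticalTypes(parc60, seq_len(60), seed = 2, noise = 0.1)
  expect_identical(nlevels(droplevels(types60)), 6L)
  ## excluded band is contiguous in the axis ordering when noise = 0
  excl <- as.integer(types) <= 2
  expect_identical(which(excl), seq_len(sum(excl)))
})

test_that("the one-call simulator is seed-deterministic", {
  cfg <- simulationConfig(seed = 11, nParcels = 30, meshSubdivisions = 2)
  s1 <- simulateCortex(cfg)
  s2 <- simulateCortex(cfg)
  expect_identical(values(s1$thickness), values(s2$thickness))
  expect_identical(s1$ec, s2$ec)
  expect_identical(s1$fc, s2$fc)
  expect_identical(parcelLabels(s1$parcellation), parcelLabels(s2$parcellation))
})
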