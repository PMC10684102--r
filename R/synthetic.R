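## Synthetic-cortex generator: every input the pipeline needs, with the
## statistical structure the downstream analyses assume (planted axis of
## supra/infragranular dominance, curvature coupling, planted hierarchy,
## distance- and similarity-dependent connectivity), all driven by one seed.

#' Construct a simulation configuration
#'
#' Returns a [SimulationConfig-class] holding every knob of the synthetic
#' cortex. The defaults define the reference study conditions used throughout
#' the package tests: a 10,242-vertex icosphere hemisphere stand-in (radius
#' 100 mm) with 500 contiguous parcels, cortex-average laminar fractions of
#' roughly (8, 6, 25, 7, 25, 29)% for layers I..VI, a planted axis along
#' which layers II-IV thicken and layers V-VI thin (with a log-quadratic
#' trajectory component so profile composition keeps rotating at the axis
#' poles), spatially autocorrelated log-scale noise (correlation length 6 mm,
#' sd 0.06), and a
#' curvature-to-superficial-thickness coupling strong enough to reproduce a
#' moderate negative curvature/superficial-fraction correlation before
#' smoothing.
#'
#' @param seed integer master seed; fully determines all generated objects.
#' @param nParcels,meshSubdivisions,radius geometry (see slots).
#' @param axisDirection planted axis direction (normalized internally).
#' @param baseFractions,axisSlopes,axisQuadratic layer composition and
#'   per-layer log-linear and log-quadratic trends along the axis (the
#'   quadratic rotates the trajectory so covariance stays graded at the axis
#'   poles while the monotone layer trends are preserved).
#' @param curvatureCoupling,spatialSmoothness,noiseSd thickness-field knobs.
#' @param ecBase,ecHierarchyGain,ecDecayLength,ecNoiseSd,hierarchySpread
#'   directed-connectivity generator.
#' @param beta0,betaLtc,betaGd binary-SC logistic coefficients (standardized
#'   predictors).
#' @param fcDecayLength,fcLtcCoupling,fcNoiseSd FC generator.
#' @param typeNoise cortical-type label-noise rate.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, nParcels = 50, meshSubdivisions = 3)
#' @export
simulationConfig <- function(seed = 1L,
                             nParcels = 500L,
                             meshSubdivisions = 5L,
                             radius = 100,
                             axisDirection = c(0, 0, 1),
                             baseFractions = c(0.08, 0.06, 0.25, 0.07, 0.25, 0.29),
                             axisSlopes = c(0, 0.5, 0.9, 0.3, -0.5, -0.95),
                             axisQuadratic = c(2.4, 0.2, -0.45, 0.15, 0.1, -0.2),
                             curvatureCoupling = 0.6,
                             spatialSmoothness = 6,
                             noiseSd = 0.06,
                             ecBase = 1,
                             ecHierarchyGain = 0.3,
                             ecDecayLength = 100,
                             ecNoiseSd = 0.02,
                             hierarchySpread = 1,
                             beta0 = -1,
                             betaLtc = 1,
                             betaGd = -1.5,
                             fcDecayLength = 60,
                             fcLtcCoupling = 0.05,
                             fcNoiseSd = 0.1,
                             typeNoise = 0.1) {
  axisDirection <- axisDirection / sqrt(sum(axisDirection^2))
  baseFractions <- baseFractions / sum(baseFractions)
  new("SimulationConfig", seed = as.integer(seed),
      nParcels = as.integer(nParcels),
      meshSubdivisions = as.integer(meshSubdivisions), radius = radius,
      axisDirection = axisDirection, baseFractions = baseFractions,
      axisSlopes = axisSlopes, axisQuadratic = axisQuadratic,
      curvatureCoupling = curvatureCoupling,
      spatialSmoothness = spatialSmoothness, noiseSd = noiseSd,
      ecBase = ecBase, ecHierarchyGain = ecHierarchyGain,
      ecDecayLength = ecDecayLength, ecNoiseSd = ecNoiseSd,
      hierarchySpread = hierarchySpread, beta0 = beta0, betaLtc = betaLtc,
      betaGd = betaGd, fcDecayLength = fcDecayLength,
      fcLtcCoupling = fcLtcCoupling, fcNoiseSd = fcNoiseSd,
      typeNoise = typeNoise)
}

## Spatially correlated standard-normal field: white noise smoothed with the
## disk smoother (radius = correlation length), re-standardized. Reuses the
## tested smoothing machinery so autocorrelation is controlled by one knob.
.smoothField <- function(mesh, radiusMm, seed, ncol = 1L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(nVertices(mesh) * ncol), ncol = ncol)
  s <- diskSmooth(x, mesh, radiusMm)
  scale(s)[, , drop = FALSE]
}

#' Build a spatially contiguous parcellation of a mesh
#'
#' Parcels are Voronoi-like patches: `nParcels` seed vertices are chosen by
#' farthest-point sampling on the mesh graph metric, and every vertex joins
#' its geodesically nearest seed. All parcels are contiguous and nonempty;
#' centroids are exact Euclidean medoids.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param nParcels number of parcels (`<= V`).
#' @param seed integer seed (first seed vertex is drawn at random).
#' @return A [Parcellation-class] with all parcels included.
#' @export
makeParcellation <- function(mesh, nParcels, seed = 1L) {
  v <- nVertices(mesh)
  if (nParcels > v) stop("nParcels must not exceed the vertex count")
  if (nParcels < 1L) stop("nParcels must be >= 1")
  g <- .meshGraph(mesh, ring = 1L)
  w <- igraph::E(g)$weight
  set.seed(.splitSeed(seed, 8L))
  seeds <- integer(nParcels)
  seeds[1L] <- sample.int(v, 1L)
  dmat <- matrix(NA_real_, nParcels, v)
  dmat[1L, ] <- igraph::distances(g, v = seeds[1L], weights = w)
  minDist <- dmat[1L, ]
  for (k in seq_len(nParcels - 1L) + 1L) {
    seeds[k] <- which.max(minDist)
    dmat[k, ] <- igraph::distances(g, v = seeds[k], weights = w)
    minDist <- pmin(minDist, dmat[k, ])
  }
  labels <- max.col(-t(dmat), ties.method = "first")
  labels <- as.integer(labels)
  new("Parcellation", labels = labels,
      includedMask = rep(TRUE, nParcels),
      centroidVertex = parcelCentroids(mesh, labels))
}

#' Sample a synthetic laminar thickness field
#'
#' Generates a 6-layer thickness map with three planted structures: (i) a
#' monotone axis `a(v)` (the vertex coordinate projected on
#' `axisDirection`, rescaled to `[0, 1]`) along which the relative thickness
#' of layers II-IV increases and of layers V-VI decreases; (ii) a
#' high-spatial-frequency synthetic curvature field whose positive (convex)
#' values thin the superficial layers I-III in proportion to
#' `curvatureCoupling`; (iii) spatially correlated log-scale noise with
#' correlation length `spatialSmoothness`. Layer fractions are formed by a
#' softmax over per-layer log-trends, so all thicknesses are strictly
#' positive by construction, and are scaled by a smoothly varying total
#' cortical thickness around 2.5 mm.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param config a [SimulationConfig-class].
#' @return A list with elements `thickness` (a
#'   [LaminarThicknessMap-class]), `axis` (per-vertex planted axis in
#'   `[0, 1]`) and `curvature` (per-vertex synthetic curvature field).
#' @export
sampleLaminarThickness <- function(mesh, config) {
  v <- nVertices(mesh)
  a <- as.vector(mesh@vertices %*% config@axisDirection)
  a <- (a - min(a)) / (max(a) - min(a))

  curv <- as.vector(.smoothField(mesh, 4, .splitSeed(config@seed, 2L))) * 0.15

  noise <- if (config@noiseSd > 0) {
    .smoothField(mesh, config@spatialSmoothness, .splitSeed(config@seed, 1L),
                 ncol = 6L) * config@noiseSd
  } else matrix(0, v, 6L)

  logits <- matrix(log(config@baseFractions), v, 6L, byrow = TRUE) +
    outer(a - 0.5, config@axisSlopes) +
    outer((a - 0.5)^2 - 1 / 12, config@axisQuadratic) + noise
  logits[, 1:3] <- logits[, 1:3] - config@curvatureCoupling * curv
  frac <- exp(logits)
  frac <- frac / rowSums(frac)

  total <- if (config@noiseSd > 0) {
    2.5 * exp(0.06 * as.vector(
      .smoothField(mesh, config@spatialSmoothness, .splitSeed(config@seed, 3L))))
  } else rep(2.5, v)

  th <- frac * total
  list(thickness = new("LaminarThicknessMap", thickness = th,
                       validMask = rep(TRUE, v)),
       axis = a, curvature = curv)
}

#' Sample synthetic depth-intensity profiles
#'
#' Per vertex, a piecewise-constant density function over cortical depth with
#' one level per layer; the levels vary smoothly across the surface and
#' drift along the planted axis (layer IV most strongly), emulating the
#' rostro-caudal densification seen in cell-stained atlases. Layer boundaries
#' in depth-fraction space equal the cumulative relative thickness, and the
#' function is sampled at `nDepths` equispaced depth-bin midpoints from pial
#' to white.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param laminarMap a [LaminarThicknessMap-class] (defines the boundaries).
#' @param config a [SimulationConfig-class].
#' @param nDepths number of depth samples (default 50).
#' @param baseLevels per-layer mean intensity levels.
#' @param levelSlopes per-layer linear drift along the planted axis (layer IV
#'   strongest by default).
#' @param levelNoiseSd per-vertex level noise sd.
#' @return An [IntensityProfileMap-class].
#' @export
sampleIntensityProfiles <- function(mesh, laminarMap, config, nDepths = 50L,
                                    baseLevels = c(1.00, 1.10, 0.95, 1.25,
                                                   1.00, 0.90),
                                    levelSlopes = c(0.05, 0.10, 0.15, 0.40,
                                                    0.05, 0.02),
                                    levelNoiseSd = 0.03) {
  v <- nrow(laminarMap@thickness)
  a <- as.vector(mesh@vertices %*% config@axisDirection)
  a <- (a - min(a)) / (max(a) - min(a))

  set.seed(.splitSeed(config@seed, 4L))
  levelNoise <- if (levelNoiseSd > 0)
    matrix(stats::rnorm(v * 6L, sd = levelNoiseSd), v, 6L) else 0
  levels <- matrix(baseLevels, v, 6L, byrow = TRUE) +
    outer(a - 0.5, levelSlopes) + levelNoise

  fr <- laminarMap@thickness / rowSums(laminarMap@thickness)
  bounds <- t(apply(fr, 1L, cumsum))      # V x 6 upper boundaries
  depths <- (seq_len(nDepths) - 0.5) / nDepths
  prof <- matrix(NA_real_, v, nDepths)
  for (k in seq_len(nDepths)) {
    layer <- rowSums(bounds < depths[k]) + 1L
    layer[layer > 6L] <- 6L
    prof[, k] <- levels[cbind(seq_len(v), layer)]
  }
  new("IntensityProfileMap", profile = prof, depthFractions = depths)
}

#' Sample directed (effective) connectivity with a planted hierarchy
#'
#' Node hierarchy scores `h` are drawn i.i.d. normal with sd
#' `hierarchySpread`. The weight of source i on target j is
#' `exp(-d_ij / ecDecayLength) * ecBase * exp(ecHierarchyGain * (h_i - h_j))`
#' plus Gaussian noise: magnitudes decay with geodesic distance, and the
#' asymmetry `A_ij - A_ji` grows monotonically with `h_i - h_j`, so
#' hierarchically higher nodes drive lower ones. [asymmetryHierarchy()]
#' recovers `h` up to monotone scaling.
#'
#' @param mesh a [SurfaceMesh-class] (for centroid geodesic distances).
#' @param parcellation a [Parcellation-class] (>= 2 included parcels).
#' @param config a [SimulationConfig-class].
#' @param gd optional precomputed P x P geodesic distance matrix.
#' @param hierarchy optional externally planted per-parcel hierarchy.
#' @return List with `ec` (P x P matrix, NA diagonal) and `hierarchy`.
#' @export
sampleEffectiveConnectivity <- function(mesh, parcellation, config,
                                        gd = NULL, hierarchy = NULL) {
  inc <- includedParcels(parcellation)
  p <- length(inc)
  if (p < 2L) stop("need at least 2 included parcels")
  if (is.null(gd))
    gd <- geodesicParcelDistance(mesh, parcellation)[inc, inc, drop = FALSE]
  set.seed(.splitSeed(config@seed, 5L))
  h <- if (is.null(hierarchy))
    stats::rnorm(p, sd = config@hierarchySpread) else hierarchy
  dh <- outer(h, h, "-")
  ec <- exp(-gd / config@ecDecayLength) * config@ecBase *
    exp(config@ecHierarchyGain * dh)
  if (config@ecNoiseSd > 0)
    ec <- ec + matrix(stats::rnorm(p * p, sd = config@ecNoiseSd), p, p)
  diag(ec) <- NA_real_
  dimnames(ec) <- list(inc, inc)
  list(ec = ec, hierarchy = h)
}

#' Sample binary structural and continuous functional connectivity
#'
#' Plants the two headline dependencies of the connectome analyses:
#' SC is Bernoulli with log-odds linear in (standardized) laminar-similarity
#' and geodesic distance, `logit p = beta0 + betaLtc * z(ltc) + betaGd *
#' z(gd)`; FC is `exp(-gd / fcDecayLength) + fcLtcCoupling * z(ltc)` plus
#' Gaussian noise. Both are generated on lower-triangle edges and mirrored,
#' so the outputs are exactly symmetric.
#'
#' @param ltc,gd aligned P x P matrices (NA diagonal allowed) or equal-length
#'   edge vectors.
#' @param config a [SimulationConfig-class].
#' @return If matrices were supplied, a list with `sc` and `fc` matrices
#'   (NA diagonal); otherwise a list with `sc` and `fc` edge vectors.
#' @export
sampleScFc <- function(ltc, gd, config) {
  asMat <- is.matrix(ltc)
  if (asMat) {
    stopifnot(is.matrix(gd), all(dim(ltc) == dim(gd)))
    idx <- .lowerPairs(nrow(ltc))
    ltcE <- ltc[idx]; gdE <- gd[idx]
  } else {
    stopifnot(length(ltc) == length(gd))
    ltcE <- ltc; gdE <- gd
  }
  zl <- .standardize(ltcE, "ltc edge vector")
  zg <- .standardize(gdE, "gd edge vector")
  set.seed(.splitSeed(config@seed, 6L))
  eta <- config@beta0 + config@betaLtc * zl + config@betaGd * zg
  sc <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
  fc <- exp(-gdE / config@fcDecayLength) + config@fcLtcCoupling * zl
  if (config@fcNoiseSd > 0)
    fc <- fc + stats::rnorm(length(fc), sd = config@fcNoiseSd)
  if (!asMat) return(list(sc = sc, fc = fc))
  p <- nrow(ltc)
  list(sc = .edgesToMatrix(idx[, 1], idx[, 2], sc, p, dimnames(ltc)),
       fc = .edgesToMatrix(idx[, 1], idx[, 2], fc, p, dimnames(ltc)))
}

#' Assign ordered cortical types along the planted axis
#'
#' Six ordered types (agranular, dysgranular, eulaminate I-III, koniocortex)
#' from sextiles of the per-parcel planted-axis value, with optional label
#' noise (each parcel independently shifted one type up or down with
#' probability `noise`). The a-/dysgranular types concentrate at the low
#' pole of the axis, so exclusion masking removes a contiguous band.
#'
#' @param parcellation a [Parcellation-class].
#' @param plantedAxis per-parcel axis values (e.g. parcellated `axis` from
#'   [sampleLaminarThickness()]).
#' @param seed integer.
#' @param noise label-noise probability in `[0, 1]`.
#' @return Factor of length P with levels [corticalTypeLevels()].
#' @export
assignCorticalTypes <- function(parcellation, plantedAxis, seed = 1L,
                                noise = 0.1) {
  p <- nParcels(parcellation)
  stopifnot(length(plantedAxis) == p)
  r <- rank(plantedAxis, ties.method = "first")
  type <- ceiling(6 * r / p)
  if (noise > 0) {
    set.seed(.splitSeed(seed, 7L))
    flip <- stats::runif(p) < noise
    shift <- sample(c(-1L, 1L), p, replace = TRUE)
    type[flip] <- .clamp(type[flip] + shift[flip], 1L, 6L)
  }
  factor(corticalTypeLevels()[type], levels = corticalTypeLevels())
}

#' Simulate a complete synthetic cortex
#'
#' One-call generator for all pipeline inputs: mesh, parcellation, laminar
#' thickness (+ planted axis and curvature), depth-intensity profiles,
#' cortical types, geodesic distances, directed connectivity (+ planted
#' hierarchy), and SC/FC planted on a generative laminar-similarity matrix
#' (partial-correlation LTC of the unsmoothed parcel profiles).
#'
#' @param config a [SimulationConfig-class].
#' @return A named list with components `config`, `mesh`, `parcellation`,
#'   `thickness`, `axis`, `curvature`, `profiles`, `types`, `gd`, `ec`,
#'   `hierarchy`, `ltcGenerative`, `sc`, `fc`.
#' @export
simulateCortex <- function(config = simulationConfig()) {
  mesh <- makeIcosphere(config@meshSubdivisions, config@radius)
  parc <- makeParcellation(mesh, config@nParcels, config@seed)
  lam <- sampleLaminarThickness(mesh, config)
  profiles <- sampleIntensityProfiles(mesh, lam$thickness, config)
  parcelAxis <- parcellate(lam$axis, parc)[, 1L]
  types <- assignCorticalTypes(parc, parcelAxis, config@seed,
                               noise = config@typeNoise)
  gd <- geodesicParcelDistance(mesh, parc)
  ecRes <- sampleEffectiveConnectivity(mesh, parc, config, gd = gd)
  relParcel <- parcellate(relativeThickness(lam$thickness), parc)
  ltcGen <- buildLTC(relParcel)
  scfc <- sampleScFc(ltcGen@values, gd, config)
  list(config = config, mesh = mesh, parcellation = parc,
       thickness = lam$thickness, axis = lam$axis, curvature = lam$curvature,
       profiles = profiles, types = types, gd = gd, ec = ecRes$ec,
       hierarchy = ecRes$hierarchy, ltcGenerative = ltcGen,
       sc = scfc$sc, fc = scfc$fc)
}
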