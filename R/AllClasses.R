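#' @import methods
NULL

#' Triangulated cortical surface mesh
#'
#' A closed, sphere-topology triangulated mesh with one primary coordinate set
#' (the midsurface, in mm) and named companion coordinate sets sharing the same
#' vertex count and order. Companions conventionally include `"sphere"` (unit
#' sphere coordinates, used by spin permutations) and `"inflated"` (used by
#' disk smoothing).
#'
#' @slot vertices numeric V x 3 matrix of midsurface coordinates (mm).
#' @slot triangles integer T x 3 matrix of 1-based vertex indices.
#' @slot companions named list of V x 3 coordinate matrices.
#'
#' @seealso [makeIcosphere()], [readSurfaceGifti()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 companions = "list"))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@triangles
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("triangles must have 3 columns")
  if (any(f < 1L) || any(f > nrow(v)))
    return("triangle indices must lie in [1, V]")
  for (nm in names(object@companions)) {
    cc <- object@companions[[nm]]
    if (!is.matrix(cc) || nrow(cc) != nrow(v) || ncol(cc) != 3L)
      return(sprintf("companion coordinate set '%s' must be a V x 3 matrix", nm))
  }
  TRUE
})

#' Surface parcellation
#'
#' Per-vertex parcel labels with a per-parcel inclusion mask (used for
#' agranular/dysgranular exclusion) and per-parcel centroid vertices. Label 0
#' is the reserved sentinel for off-parcel vertices.
#'
#' @slot labels integer vector, one label per vertex, in `{0, 1, ..., P}`.
#' @slot includedMask logical vector of length P.
#' @slot centroidVertex integer vector of length P: medoid vertex per parcel.
#'
#' @seealso [makeParcellation()], [excludeRegions()], [parcelCentroids()]
#' @export
setClass("Parcellation",
  representation(labels = "integer", includedMask = "logical",
                 centroidVertex = "integer"))

setValidity("Parcellation", function(object) {
  p <- length(object@includedMask)
  if (length(object@centroidVertex) != p)
    return("centroidVertex and includedMask must have one entry per parcel")
  if (any(object@labels < 0L) || any(object@labels > p))
    return("labels must lie in {0, ..., P}")
  counts <- tabulate(object@labels, nbins = p)
  if (any(counts[object@includedMask] < 1L))
    return("every included parcel must contain at least one vertex")
  cv <- object@centroidVertex
  ok <- is.na(cv) | object@labels[cv] == seq_len(p)
  if (!all(ok)) return("centroidVertex must belong to its own parcel")
  TRUE
})

#' Per-vertex laminar thickness map
#'
#' Absolute thickness of the six isocortical layers (I..VI) at each vertex,
#' in mm. Invalid vertices (e.g. excluded regions) carry NA in all layers and
#' FALSE in `validMask`.
#'
#' @slot thickness numeric V x 6 matrix (mm).
#' @slot validMask logical vector of length V.
#' @export
setClass("LaminarThicknessMap",
  representation(thickness = "matrix", validMask = "logical"))

setValidity("LaminarThicknessMap", function(object) {
  th <- object@thickness
  if (ncol(th) != 6L) return("thickness must have 6 columns (layers I..VI)")
  if (length(object@validMask) != nrow(th))
    return("validMask length must equal the vertex count")
  v <- th[object@validMask, , drop = FALSE]
  if (length(v) && (any(!is.finite(v)) || any(v <= 0)))
    return("valid thickness entries must be finite and > 0")
  TRUE
})

#' Relative laminar thickness (depth-fraction) profiles
#'
#' Layer thicknesses divided by total cortical thickness; each valid row sums
#' to 1. Rows may index vertices or parcels.
#'
#' @slot fractions numeric N x 6 matrix in `[0, 1]`.
#' @slot validMask logical vector of length N.
#' @export
setClass("RelativeLaminarMap",
  representation(fractions = "matrix", validMask = "logical"))

setValidity("RelativeLaminarMap", function(object) {
  fr <- object@fractions
  if (length(object@validMask) != nrow(fr))
    return("validMask length must equal the row count")
  v <- fr[object@validMask, , drop = FALSE]
  if (length(v)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      return("valid fractions must be finite and in [0, 1]")
    if (any(abs(rowSums(v) - 1) > 1e-9))
      return("valid rows must sum to 1 (tolerance 1e-9)")
  }
  TRUE
})

#' Depth-sampled intensity profiles
#'
#' Image-intensity (cell-stain density) profiles sampled at D depth fractions
#' from the pial (0) to the white (1) surface, one row per vertex.
#'
#' @slot profile numeric V x D matrix, unitless intensities.
#' @slot depthFractions numeric vector of D strictly increasing values in `[0, 1]`.
#' @export
setClass("IntensityProfileMap",
  representation(profile = "matrix", depthFractions = "numeric"))

setValidity("IntensityProfileMap", function(object) {
  d <- object@depthFractions
  if (length(d) != ncol(object@profile))
    return("depthFractions length must equal the profile column count")
  if (any(diff(d) <= 0)) return("depthFractions must be strictly increasing")
  if (any(d < 0) || any(d > 1)) return("depthFractions must lie in [0, 1]")
  TRUE
})

#' Parcel-by-parcel covariance/similarity matrix
#'
#' Symmetric similarity between parcel profiles: laminar thickness covariance
#' (LTC), laminar intensity covariance (LIC), microstructural profile
#' covariance (MPC), or alternative metrics. The diagonal is undefined (NA)
#' by convention (the Fisher z transform diverges at r = 1) and is excluded
#' from every downstream statistic.
#'
#' @slot values numeric P x P matrix with NA diagonal; dimnames carry parcel ids.
#' @slot kind character: one of "LTC", "LIC", "MPC", "pearson", "euclidean".
#' @slot fisherZ logical: whether values are arctanh-transformed correlations.
#'
#' @seealso [buildLTC()], [buildProfileCovariance()]
#' @export
setClass("CovarianceMatrix",
  representation(values = "matrix", kind = "character", fisherZ = "logical"))

setValidity("CovarianceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (!all(is.na(diag(v)))) return("diagonal must be undefined (NA)")
  off <- v; diag(off) <- 0
  offT <- t(v); diag(offT) <- 0
  both <- !is.na(off) & !is.na(offT)
  if (any(abs(off[both] - offT[both]) > 1e-10))
    return("values must be symmetric to 1e-10")
  TRUE
})

#' Gradient (principal-axis) embedding result
#'
#' @slot loadings numeric P x C matrix of per-parcel axis loadings
#'   (rownames carry parcel ids).
#' @slot explainedVariance numeric vector of C descending fractions in `[0, 1]`.
#' @slot method character: "pca", "diffusion" or "laplacian".
#' @slot sparsity numeric: the row-sparsification proportion p used upstream
#'   (NA when the affinity was supplied directly).
#' @slot signFlips logical vector of length C: whether each component was
#'   flipped to align with a reference map.
#'
#' @seealso [computeGradients()], [covarianceGradients()]
#' @export
setClass("GradientResult",
  representation(loadings = "matrix", explainedVariance = "numeric",
                 method = "character", sparsity = "numeric",
                 signFlips = "logical"))

setValidity("GradientResult", function(object) {
  ev <- object@explainedVariance
  if (length(ev) != ncol(object@loadings))
    return("explainedVariance must have one entry per component")
  if (any(ev < -1e-12) || any(ev > 1 + 1e-12) || sum(ev) > 1 + 1e-8)
    return("explainedVariance fractions must lie in [0, 1] and sum to <= 1")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-12))
    return("explainedVariance must be non-increasing")
  TRUE
})

#' K-means clustering result with elbow selection
#'
#' @slot labels integer vector of cluster labels (1..k) at the chosen k.
#' @slot distortion named numeric: mean within-cluster sum of squares per
#'   candidate k.
#' @slot chosenK integer: the elbow of the distortion curve.
#' @seealso [kmeansElbow()]
#' @export
setClass("ClusterResult",
  representation(labels = "integer", distortion = "numeric",
                 chosenK = "integer"))

#' Permutation/surrogate null distribution
#'
#' Holds an observed statistic, its null statistics, and the permutation
#' p-value under the add-one convention
#' `p = (1 + #{null at least as extreme}) / (nPerm + 1)`, which is never 0.
#'
#' @slot observed numeric scalar.
#' @slot nulls numeric vector of length nPerm.
#' @slot pValue numeric in (0, 1].
#' @slot tail character: "two.sided", "greater" or "less".
#' @slot nPerm integer.
#' @slot seed integer seed that generated the nulls.
#' @seealso [correlationTest()]
#' @export
setClass("NullDistribution",
  representation(observed = "numeric", nulls = "numeric", pValue = "numeric",
                 tail = "character", nPerm = "integer", seed = "integer"))

setValidity("NullDistribution", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' Variogram-matched surrogate ensemble
#'
#' @slot surrogates numeric n x P matrix, one surrogate map per row.
#' @slot diagnostics data.frame with per-surrogate variogram-fit records
#'   (chosen k, alpha, beta, SSE).
#' @slot seed integer.
#' @seealso [variogramSurrogates()]
#' @export
setClass("SurrogateEnsemble",
  representation(surrogates = "matrix", diagnostics = "data.frame",
                 seed = "integer"))

#' Model fit summary
#'
#' @slot model character tag ("exponential", "logistic", "correlation").
#' @slot coefficients named numeric.
#' @slot gof numeric goodness of fit (R-squared or pseudo R-squared).
#' @slot gofType character ("r.squared", "mcfadden", "coxsnell", "estimate").
#' @slot pValue numeric permutation p (NA when no null was requested).
#' @slot nEdges integer number of defined edges/points used.
#' @slot extra list of auxiliary results (fitted values, null distribution, ...).
#' @export
setClass("FitResult",
  representation(model = "character", coefficients = "numeric",
                 gof = "numeric", gofType = "character", pValue = "numeric",
                 nEdges = "integer", extra = "list"))

#' Synthetic-cortex simulation configuration
#'
#' One integer seed fully determines every generated object; module-level
#' seeds are derived from it by a deterministic splitting scheme so the
#' generators can be exercised independently.
#'
#' Geometry defaults emulate a single hemisphere at roughly the working
#' resolution of a downsampled histological surface: a subdivision-5
#' icosphere (10,242 vertices) of radius 100 mm carrying 500 spatially
#' contiguous parcels.
#'
#' @slot seed integer master seed.
#' @slot nParcels integer number of parcels.
#' @slot meshSubdivisions integer icosphere subdivision level.
#' @slot radius numeric sphere radius (mm).
#' @slot axisDirection numeric unit 3-vector: the planted axis of
#'   supragranular-to-infragranular dominance.
#' @slot baseFractions numeric 6-vector: cortex-average relative laminar
#'   thickness (layers I..VI), summing to 1.
#' @slot axisSlopes numeric 6-vector: per-layer log-linear trend along the
#'   planted axis (positive = thickens towards the axis top).
#' @slot axisQuadratic numeric 6-vector: per-layer log-quadratic component of
#'   the trajectory; rotates the profile-composition direction along the axis
#'   so that end-of-axis parcels remain distinguishable, without breaking the
#'   monotone supragranular/infragranular trends.
#' @slot curvatureCoupling numeric: strength of the curvature to
#'   superficial-thickness coupling (logit units per curvature unit).
#' @slot spatialSmoothness numeric: correlation length (mm) of the spatially
#'   smoothed thickness noise.
#' @slot noiseSd numeric: per-layer log-scale noise standard deviation.
#' @slot ecBase,ecHierarchyGain,ecDecayLength,ecNoiseSd numeric: directed
#'   connectivity generator (baseline weight, hierarchy asymmetry gain,
#'   distance decay length in mm, additive noise sd).
#' @slot hierarchySpread numeric sd of the planted node hierarchy.
#' @slot beta0,betaLtc,betaGd numeric logistic coefficients of the binary SC
#'   generator (on standardized predictors).
#' @slot fcDecayLength numeric FC exponential decay length (mm).
#' @slot fcLtcCoupling numeric FC-LTC coupling gamma.
#' @slot fcNoiseSd numeric FC additive noise sd.
#' @slot typeNoise numeric label-noise rate of the cortical-type generator.
#' @seealso [simulationConfig()], [simulateCortex()]
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nParcels = "integer",
                 meshSubdivisions = "integer", radius = "numeric",
                 axisDirection = "numeric", baseFractions = "numeric",
                 axisSlopes = "numeric", axisQuadratic = "numeric",
                 curvatureCoupling = "numeric",
                 spatialSmoothness = "numeric", noiseSd = "numeric",
                 ecBase = "numeric", ecHierarchyGain = "numeric",
                 ecDecayLength = "numeric", ecNoiseSd = "numeric",
                 hierarchySpread = "numeric",
                 beta0 = "numeric", betaLtc = "numeric", betaGd = "numeric",
                 fcDecayLength = "numeric", fcLtcCoupling = "numeric",
                 fcNoiseSd = "numeric", typeNoise = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@radius <= 0) return("radius must be > 0")
  if (object@spatialSmoothness <= 0) return("spatialSmoothness must be > 0")
  if (object@ecDecayLength <= 0 || object@fcDecayLength <= 0)
    return("decay lengths must be > 0")
  if (length(object@axisDirection) != 3L)
    return("axisDirection must be a 3-vector")
  if (length(object@baseFractions) != 6L || length(object@axisSlopes) != 6L ||
      length(object@axisQuadratic) != 6L)
    return("baseFractions, axisSlopes and axisQuadratic must be 6-vectors")
  if (any(object@baseFractions <= 0))
    return("baseFractions must be positive")
  TRUE
})
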