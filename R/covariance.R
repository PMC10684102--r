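## Relative-thickness profiles and the covariance matrices built from them
## (LTC and alternatives, MPC, LIC, fused LTC+LIC, intraregional homogeneity).

#' Relative laminar thickness
#'
#' Divides each row of a 6-layer thickness map by its total cortical
#' thickness, yielding depth-fraction profiles that sum to 1. The valid mask
#' is propagated; a non-positive total at a valid row is an error (it would
#' silently corrupt every downstream correlation).
#'
#' @param laminar a [LaminarThicknessMap-class] or plain N x 6 matrix.
#' @return A [RelativeLaminarMap-class].
#' @export
relativeThickness <- function(laminar) {
  if (is(laminar, "LaminarThicknessMap")) {
    th <- laminar@thickness
    mask <- laminar@validMask
  } else {
    th <- laminar
    mask <- rowSums(is.na(th)) == 0L
  }
  tot <- rowSums(th)
  bad <- mask & (!is.finite(tot) | tot <= 0)
  if (any(bad))
    stop("non-positive total thickness at valid row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  fr <- th / tot
  fr[!mask, ] <- NA_real_
  new("RelativeLaminarMap", fractions = fr, validMask = mask)
}

#' First-order partial correlation of two profiles
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`: the
#' correlation of x and y after removing the shared linear dependence on the
#' covariate z (here, the cortex-average laminar profile). Equivalent to
#' correlating the least-squares residuals of x on z and y on z.
#'
#' @param x,y,z numeric vectors of equal length K >= 4; each non-constant,
#'   and neither x nor y perfectly collinear with z.
#' @return Scalar in `[-1, 1]`.
#' @export
profilePartialCorrelation <- function(x, y, z) {
  k <- length(x)
  if (length(y) != k || length(z) != k) stop("x, y, z must have equal length")
  if (k < 4L) stop("profiles must have at least 4 entries")
  for (nm in c("x", "y", "z")) {
    v <- get(nm)
    if (stats::sd(v) == 0)
      stop("undefined result: input '", nm, "' is constant")
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-14 || abs(ryz) >= 1 - 1e-14)
    stop("undefined result: profile perfectly collinear with the covariate")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

## All pairwise partial correlations of the rows of X against covariate z.
## Returns a symmetric matrix with NA diagonal. Errors mirror
## profilePartialCorrelation but report offending rows/pairs collectively.
.partialCorMatrix <- function(x, z) {
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("undefined result: constant profile at parcel(s) ",
         paste(utils::head(which(sds == 0), 5L), collapse = ", "))
  if (stats::sd(z) == 0) stop("undefined result: constant covariate profile")
  cc <- stats::cor(t(x))
  rz <- as.vector(stats::cor(t(x), z))
  if (any(abs(rz) >= 1 - 1e-14))
    stop("undefined result: profile(s) perfectly collinear with the covariate: ",
         paste(utils::head(which(abs(rz) >= 1 - 1e-14), 5L), collapse = ", "))
  den <- sqrt(1 - rz^2)
  pc <- (cc - outer(rz, rz)) / outer(den, den)
  diag(pc) <- NA_real_
  pc
}

#' Build a laminar covariance matrix
#'
#' Pairwise similarity of parcel profiles. With `metric = "partial"` (the
#' laminar thickness covariance construction), each pair is the first-order
#' partial correlation controlling for the average profile over the supplied
#' parcels (the "greater-than-average" covariance), then Fisher
#' z-transformed (`arctanh`). `"pearson"` is the plain correlation plus
#' Fisher z; `"euclidean"` is the negated Euclidean distance between
#' profiles (negated so that larger always means more similar), with no
#' Fisher z. The diagonal is undefined.
#'
#' Partial/Pearson correlations are clipped to `1 - 1e-15` in magnitude
#' before `arctanh`, so numerically identical profiles give a finite, maximal
#' entry rather than an infinity; exact collinearity with the covariate is
#' still an error.
#'
#' @param profiles numeric P x K matrix of parcel profiles (rownames = parcel
#'   ids), or a [RelativeLaminarMap-class] over parcels. Rows with NA are
#'   dropped with a warning.
#' @param covariate covariate profile (default: unweighted column mean over
#'   the supplied parcels).
#' @param metric `"partial"`, `"pearson"` or `"euclidean"`.
#' @param kind label stored in the result (default `"LTC"`).
#' @return A [CovarianceMatrix-class].
#' @examples
#' prof <- matrix(runif(60, 0.5, 1.5), 10, 6)
#' prof <- prof / rowSums(prof)
#' ltc <- buildLTC(prof)
#' @export
buildLTC <- function(profiles, covariate = NULL,
                     metric = c("partial", "pearson", "euclidean"),
                     kind = "LTC") {
  metric <- match.arg(metric)
  if (is(profiles, "RelativeLaminarMap")) profiles <- values(profiles)
  if (is.null(rownames(profiles))) rownames(profiles) <- seq_len(nrow(profiles))
  drop <- rowSums(is.na(profiles)) > 0L
  if (any(drop)) {
    warning("dropping ", sum(drop), " parcel(s) with undefined profiles")
    profiles <- profiles[!drop, , drop = FALSE]
  }
  if (nrow(profiles) < 3L) stop("need at least 3 parcels")
  ids <- rownames(profiles)

  if (metric == "euclidean") {
    m <- -as.matrix(stats::dist(profiles))
    diag(m) <- NA_real_
    dimnames(m) <- list(ids, ids)
    return(new("CovarianceMatrix", values = m, kind = "euclidean",
               fisherZ = FALSE))
  }
  if (metric == "partial") {
    if (is.null(covariate)) covariate <- colMeans(profiles)
    m <- .partialCorMatrix(profiles, covariate)
  } else {
    sds <- apply(profiles, 1L, stats::sd)
    if (any(sds == 0))
      stop("undefined result: constant profile at parcel(s) ",
           paste(utils::head(which(sds == 0), 5L), collapse = ", "))
    m <- stats::cor(t(profiles))
    diag(m) <- NA_real_
  }
  m <- atanh(.clamp(m, -1 + 1e-15, 1 - 1e-15))
  dimnames(m) <- list(ids, ids)
  new("CovarianceMatrix", values = m,
      kind = if (metric == "pearson") "pearson" else kind, fisherZ = TRUE)
}

#' Microstructural profile covariance
#'
#' The same partial-correlation + Fisher-z machinery as [buildLTC()], applied
#' to depth-intensity profiles (D >= 10 samples) with the mean profile as the
#' covariate.
#'
#' @param profiles numeric P x D matrix of parcel intensity profiles.
#' @param covariate optional covariate profile (default: column means).
#' @return A [CovarianceMatrix-class] of kind `"MPC"`.
#' @export
buildProfileCovariance <- function(profiles, covariate = NULL) {
  if (ncol(profiles) < 10L)
    stop("profile covariance needs at least 10 depth samples")
  buildLTC(profiles, covariate = covariate, metric = "partial", kind = "MPC")
}

#' Mean laminar intensities from depth profiles
#'
#' For each vertex and layer, the intensity profile is linearly interpolated
#' at `samplesPerLayer` equally spaced interior points of the layer's
#' depth-fraction interval (interval boundaries from the cumulative relative
#' thickness) and averaged, yielding a V x 6 laminar intensity table. A
#' zero-thickness layer has no interior and gets NA.
#'
#' @param profiles an [IntensityProfileMap-class] (or V x D matrix, in which
#'   case `depthFractions` must be supplied).
#' @param rel a [RelativeLaminarMap-class] or V x 6 fraction matrix.
#' @param samplesPerLayer number of interior sample points per layer
#'   (default 10); 1 samples the layer midpoint.
#' @param depthFractions depth grid when `profiles` is a plain matrix.
#' @return Numeric V x 6 matrix of mean laminar intensities.
#' @export
laminarIntensity <- function(profiles, rel, samplesPerLayer = 10L,
                             depthFractions = NULL) {
  if (is(profiles, "IntensityProfileMap")) {
    depthFractions <- profiles@depthFractions
    profiles <- profiles@profile
  }
  if (is.null(depthFractions))
    stop("depthFractions must be supplied with a plain profile matrix")
  if (is(rel, "RelativeLaminarMap")) rel <- values(rel)
  v <- nrow(profiles)
  stopifnot(nrow(rel) == v)
  out <- matrix(NA_real_, v, 6L)
  offs <- (seq_len(samplesPerLayer) - 0.5) / samplesPerLayer
  for (i in seq_len(v)) {
    fr <- rel[i, ]
    if (anyNA(fr)) next
    hi <- cumsum(fr)
    lo <- c(0, hi[-6L])
    for (l in 1:6) {
      if (fr[l] <= 0) next
      pts <- lo[l] + offs * fr[l]
      out[i, l] <- mean(stats::approx(depthFractions, profiles[i, ],
                                      xout = pts, rule = 2L)$y)
    }
  }
  colnames(out) <- paste0("L", 1:6)
  out
}

#' Fuse two covariance matrices by rank alignment
#'
#' Off-diagonal entries of each matrix are replaced by their ranks; the
#' second matrix's ranks are linearly rescaled to the min-max range of the
#' first's; the matrices are then concatenated horizontally into a P x 2P
#' table whose rows can be embedded jointly (e.g. the fused laminar
#' thickness + intensity covariance). Undefined entries stay NA.
#'
#' @param ltc,lic [CovarianceMatrix-class] objects (or plain matrices) over
#'   the same parcel set.
#' @return Numeric P x 2P matrix.
#' @export
fuseMatrices <- function(ltc, lic) {
  a <- .asMatrix(ltc); b <- .asMatrix(lic)
  if (!all(dim(a) == dim(b)))
    stop("matrices must share the parcel set")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("matrices must share the parcel set (mismatched parcel ids)")
  rankOff <- function(m) {
    off <- !is.na(m)
    r <- m
    r[off] <- rank(m[off])
    r
  }
  ra <- rankOff(a); rb <- rankOff(b)
  rngA <- range(ra, na.rm = TRUE); rngB <- range(rb, na.rm = TRUE)
  if (diff(rngB) > 0) {
    rb <- (rb - rngB[1]) / diff(rngB) * diff(rngA) + rngA[1]
  } else {
    rb[!is.na(rb)] <- mean(rngA)
  }
  out <- cbind(ra, rb)
  colnames(out) <- c(paste0(colnames(a), ".1"), paste0(colnames(b), ".2"))
  out
}

#' Intraregional homogeneity of vertex-level covariance
#'
#' For each region r: the mean covariance over vertex pairs both inside r
#' minus the mean over pairs with exactly one vertex in r (diagonal
#' excluded). Positive scores mean the region is internally more coherent
#' than it is similar to the rest of the cortex; regions with fewer than 2
#' vertices are undefined.
#'
#' @param vertexCov [CovarianceMatrix-class] (or matrix) over vertices.
#' @param regionLabels per-vertex region labels (character/factor/integer).
#' @return Named numeric vector of per-region scores.
#' @export
intraregionalHomogeneity <- function(vertexCov, regionLabels) {
  m <- .asMatrix(vertexCov)
  stopifnot(nrow(m) == length(regionLabels))
  labs <- as.character(regionLabels)
  regions <- unique(labs)
  if (length(regions) < 2L) stop("need at least 2 regions")
  out <- stats::setNames(rep(NA_real_, length(regions)), regions)
  for (r in regions) {
    inR <- labs == r
    if (sum(inR) < 2L) next
    within <- m[inR, inR, drop = FALSE]
    between <- m[inR, !inR, drop = FALSE]
    out[r] <- mean(within[upper.tri(within)], na.rm = TRUE) -
      mean(between, na.rm = TRUE)
  }
  out
}
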