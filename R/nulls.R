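## Spatially constrained null models: parcel spin permutations,
## variogram-matched surrogate maps, and the permutation tests built on them.

#' Spin permutations of parcels on the sphere
#'
#' Draws `nPerm` uniform random 3D rotations (QR orthonormalization of a
#' Gaussian matrix, determinant forced to +1), applies each to the parcel
#' centroid coordinates on the sphere, and maps every parcel to the nearest
#' rotated centroid. The mapping is surjective nearest-neighbor assignment
#' (repeats permitted), the standard parcel-spin scheme; spun maps preserve
#' the spatial autocorrelation of the original because the rotation is
#' rigid.
#'
#' A spun map is obtained as `map[perms[k, ]]`; a spun matrix as
#' `m[perms[k, ], perms[k, ]]` (joint row/column conjugation, preserving
#' symmetry).
#'
#' @param sphereCoords P x 3 parcel centroid coordinates on a common sphere
#'   (radius spread beyond 1% is an error).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param bijective if TRUE, resolve the assignment greedily to a bijection
#'   (each rotated centroid used once, closest pairs first) instead of the
#'   standard repeats-permitted mapping.
#' @return Integer nPerm x P matrix of parcel indices.
#' @export
spinPermutation <- function(sphereCoords, nPerm, seed = 1L, bijective = FALSE) {
  cc <- as.matrix(sphereCoords)
  stopifnot(ncol(cc) == 3L)
  rad <- sqrt(rowSums(cc^2))
  if (any(rad == 0) || diff(range(rad)) / mean(rad) > 0.01)
    stop("centroids must lie on a common sphere (radius spread > 1%)")
  p <- nrow(cc)
  set.seed(.splitSeed(seed, 21L))
  perms <- matrix(NA_integer_, nPerm, p)
  for (k in seq_len(nPerm))
    perms[k, ] <- .spinAssign(cc, .randomRotation(), bijective)
  perms
}

## Map each rotated centroid to an original centroid index (nearest neighbor,
## or greedy closest-pairs-first bijection).
.spinAssign <- function(cc, rot, bijective = FALSE) {
  p <- nrow(cc)
  rc <- cc %*% t(rot)
  d2 <- outer(rowSums(rc^2), rowSums(cc^2), "+") - 2 * tcrossprod(rc, cc)
  if (!bijective) return(max.col(-d2, ties.method = "first"))
  ord <- order(d2)
  usedRow <- logical(p); usedCol <- logical(p)
  asg <- integer(p)
  for (idx in ord) {
    r <- (idx - 1L) %% p + 1L
    cl <- (idx - 1L) %/% p + 1L
    if (!usedRow[r] && !usedCol[cl]) {
      asg[r] <- cl
      usedRow[r] <- TRUE; usedCol[cl] <- TRUE
      if (all(usedRow)) break
    }
  }
  asg
}

.randomRotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  qr <- qr(m)
  q <- qr.Q(qr)
  q <- q %*% diag(sign(diag(qr.R(qr))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

## Kernel-smoothed empirical variogram over nBins distance bins up to the
## median pairwise distance. Returns bin centers, a (nBins x nPairs) weight
## matrix (rows normalized), and the pair index used.
.variogramSetup <- function(dist, nBins = 25L) {
  p <- nrow(dist)
  idx <- .lowerPairs(p)
  dv <- dist[idx]
  dmax <- stats::median(dv)
  keep <- which(dv <= dmax)
  dv <- dv[keep]
  centers <- seq(min(dv), dmax, length.out = nBins)
  h <- diff(centers[1:2])
  w <- exp(-((matrix(centers, nBins, length(dv)) -
              matrix(dv, nBins, length(dv), byrow = TRUE))^2) / (2 * h^2))
  w <- w / rowSums(w)
  list(idx = idx[keep, , drop = FALSE], centers = centers, weights = w)
}

## Exponentially-weighted k-nearest-neighbor smoother matrix (dense P x P,
## rows normalized).
.knnSmoother <- function(dist, k) {
  p <- nrow(dist)
  s <- matrix(0, p, p)
  for (i in seq_len(p)) {
    d <- dist[i, ]
    d[i] <- Inf
    nn <- order(d)[seq_len(k)]
    w <- exp(-d[nn] / d[nn][k])
    s[i, nn] <- w / sum(w)
  }
  s
}

#' Variogram-matched surrogate maps
#'
#' Generates random surrogate maps whose spatial variograms approximately
#' match that of the original map, for use as a spatial-autocorrelation-
#' preserving null. Per surrogate: the map values are randomly permuted;
#' the permuted map is smoothed by exponentially weighted k-nearest-neighbor
#' averaging for each candidate k in `knnSet`; the empirical smoothed
#' variogram is regressed on each smoothed surrogate's
#' (`gamma_emp ~ alpha * gamma_surr + beta`); the k with the lowest SSE
#' wins; and the surrogate is `sqrt(|alpha|) * smoothed + sqrt(|beta|) *
#' noise`. Surrogate marginals are not resampled to the original values by
#' default (the noise term changes them); set `rankRemap = TRUE` to remap
#' each surrogate's ranks onto the original values.
#'
#' @param x numeric per-parcel map (length P >= 30).
#' @param dist P x P distance matrix aligned with `x`.
#' @param nPerm number of surrogates.
#' @param seed integer seed.
#' @param knnSet candidate neighborhood sizes.
#' @param nBins number of variogram distance bins (default 25, up to the
#'   median pairwise distance).
#' @param rankRemap remap surrogate ranks onto the original value set.
#' @return A [SurrogateEnsemble-class].
#' @export
variogramSurrogates <- function(x, dist, nPerm, seed = 1L,
                                knnSet = NULL, nBins = 25L,
                                rankRemap = FALSE) {
  p <- length(x)
  stopifnot(nrow(dist) == p, ncol(dist) == p)
  if (p < 30L) stop("variogram surrogates need at least 30 parcels")
  if (any(!is.finite(dist[upper.tri(dist)])) || stats::sd(dist[upper.tri(dist)]) == 0)
    stop("degenerate distance matrix")
  if (is.null(knnSet))
    knnSet <- unique(pmin(p - 1L, c(5L, 10L, 20L, 40L)))

  vg <- .variogramSetup(dist, nBins)
  gammaOf <- function(mapMat) {
    dd <- (mapMat[vg$idx[, 1L], , drop = FALSE] -
           mapMat[vg$idx[, 2L], , drop = FALSE])^2 / 2
    vg$weights %*% dd
  }
  gEmp <- as.vector(gammaOf(matrix(x, ncol = 1L)))

  smoothers <- lapply(knnSet, function(k) .knnSmoother(dist, k))
  set.seed(.splitSeed(seed, 22L))
  permIdx <- replicate(nPerm, sample.int(p))
  xPerm <- matrix(x[permIdx], p, nPerm)

  best <- list(sse = rep(Inf, nPerm), alpha = numeric(nPerm),
               beta = numeric(nPerm), k = integer(nPerm),
               sm = matrix(0, p, nPerm))
  for (ki in seq_along(knnSet)) {
    sm <- smoothers[[ki]] %*% xPerm
    g <- gammaOf(sm)                      # nBins x nPerm
    gm <- colMeans(g)
    ge <- mean(gEmp)
    cov <- colMeans(g * gEmp) - gm * ge
    varg <- colMeans(g^2) - gm^2
    alpha <- ifelse(varg > 1e-300, cov / varg, 0)
    beta <- ge - alpha * gm
    ## the intercept feeds a white-noise term whose variogram contribution is
    ## |beta|, so a negative fit would bias surrogates upward; constrain to
    ## beta >= 0 (refit the slope through the origin)
    neg <- beta < 0
    if (any(neg)) {
      g2sum <- colMeans(g^2)
      alpha[neg] <- ifelse(g2sum[neg] > 1e-300,
                           (colMeans(g * gEmp))[neg] / g2sum[neg], 0)
      beta[neg] <- 0
    }
    resid <- gEmp - sweep(sweep(g, 2L, alpha, "*"), 2L, beta, "+")
    sse <- colSums(resid^2)
    upd <- sse < best$sse
    best$sse[upd] <- sse[upd]
    best$alpha[upd] <- alpha[upd]
    best$beta[upd] <- beta[upd]
    best$k[upd] <- knnSet[ki]
    best$sm[, upd] <- sm[, upd]
  }

  noise <- matrix(stats::rnorm(p * nPerm), p, nPerm)
  sur <- sweep(best$sm, 2L, sqrt(abs(best$alpha)), "*") +
    sweep(noise, 2L, sqrt(abs(best$beta)), "*")
  if (rankRemap) {
    sorted <- sort(x)
    sur <- apply(sur, 2L, function(s) sorted[rank(s, ties.method = "first")])
  }
  new("SurrogateEnsemble", surrogates = t(sur),
      diagnostics = data.frame(k = best$k, alpha = best$alpha,
                               beta = best$beta, sse = best$sse),
      seed = as.integer(seed))
}

#' Correlation test against spatially constrained nulls
#'
#' Computes the observed correlation of `x` and `y` and a permutation
#' p-value from a null distribution in which only `x` is permuted or
#' surrogated: spin permutations (maps or matrices) or variogram-matched
#' surrogates (maps). For matrices, the correlation is taken over the
#' mutually defined lower-triangle edges, and spins conjugate rows and
#' columns jointly. Two-sided p by `|null| >= |observed|` with the add-one
#' convention.
#'
#' @param x,y aligned maps (vectors) or P x P matrices
#'   ([CovarianceMatrix-class] accepted).
#' @param nullSource `"spin"` or `"variogram"`.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @param sphereCoords P x 3 sphere centroid coordinates (spin null).
#' @param dist P x P distance matrix (variogram null).
#' @param tail `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A [NullDistribution-class].
#' @export
correlationTest <- function(x, y, nullSource = c("spin", "variogram"),
                            nPerm = 1000L, seed = 1L,
                            method = c("pearson", "spearman"),
                            sphereCoords = NULL, dist = NULL,
                            tail = "two.sided") {
  nullSource <- match.arg(nullSource)
  method <- match.arg(method)
  xm <- .asMatrix(x); ym <- .asMatrix(y)
  isMat <- is.matrix(xm) && nrow(xm) == ncol(xm) && nrow(xm) > 3L &&
    is.matrix(ym)

  corOf <- function(a, b) {
    keep <- stats::complete.cases(cbind(a, b))
    if (sum(keep) < 3L) return(NA_real_)
    if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) return(NA_real_)
    stats::cor(a[keep], b[keep], method = method)
  }

  if (isMat) {
    idx <- .lowerPairs(nrow(xm))
    xv <- xm[idx]; yv <- ym[idx]
    if (all(is.na(xv + yv))) stop("all edges are undefined")
    obs <- corOf(xv, yv)
    if (is.na(obs)) stop("observed correlation is undefined")
    if (nullSource == "variogram")
      stop("variogram nulls apply to surface maps, not matrices; use spin")
    perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
    nulls <- vapply(seq_len(nPerm), function(k) {
      pk <- perms[k, ]
      corOf(xm[pk, pk][idx], yv)
    }, numeric(1))
  } else {
    if (length(xm) != length(ym)) stop("x and y must be aligned")
    obs <- corOf(xm, ym)
    if (is.na(obs)) stop("observed correlation is undefined")
    if (nullSource == "spin") {
      perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
      nulls <- vapply(seq_len(nPerm), function(k) corOf(xm[perms[k, ]], ym),
                      numeric(1))
    } else {
      if (is.null(dist)) stop("variogram nulls require a distance matrix")
      ens <- variogramSurrogates(xm, dist, nPerm = nPerm, seed = seed)
      nulls <- apply(ens@surrogates, 1L, corOf, b = ym)
    }
  }
  .newNullDistribution(obs, nulls, tail, seed)
}

#' One-way ANOVA of a continuous map across categorical groups, spin null
#'
#' The observed F statistic compares group means of a per-parcel continuous
#' map; significance comes from spinning the continuous map (`nPerm`
#' rotations) rather than the F distribution, so spatial autocorrelation is
#' respected. Post hoc two-sample t statistics for every group pair use the
#' same spun maps, with Bonferroni correction by the number of pairs.
#' Groups with fewer than 2 parcels are dropped with a warning. An infinite
#' observed F (zero within-group variance) counts as exceeding every null.
#'
#' @param x per-parcel continuous map.
#' @param groups per-parcel labels.
#' @param nPerm number of spins (default 1000).
#' @param seed integer seed.
#' @param sphereCoords P x 3 sphere centroid coordinates.
#' @return List with `F`, `pSpin`, and a `postHoc` data.frame (pair, t,
#'   pSpin, pBonferroni).
#' @export
anovaSpin <- function(x, groups, nPerm = 1000L, seed = 1L,
                      sphereCoords = NULL) {
  groups <- as.character(groups)
  stopifnot(length(x) == length(groups))
  keep <- !is.na(x) & !is.na(groups)
  counts <- table(groups[keep])
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("dropping group(s) with < 2 parcels: ",
            paste(small, collapse = ", "))
    keep <- keep & !(groups %in% small)
  }
  if (length(unique(groups[keep])) < 2L)
    stop("need at least 2 groups with >= 2 parcels")

  fStat <- function(v) {
    vv <- v[keep]; gg <- groups[keep]
    gm <- tapply(vv, gg, mean)
    n <- tapply(vv, gg, length)
    grand <- mean(vv)
    ssb <- sum(n * (gm[names(n)] - grand)^2)
    ssw <- sum((vv - gm[gg])^2)
    dfb <- length(n) - 1L
    dfw <- length(vv) - length(n)
    (ssb / dfb) / (ssw / dfw)
  }
  tStat <- function(v, g1, g2) {
    a <- v[keep & groups == g1]; b <- v[keep & groups == g2]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }

  fObs <- fStat(x)
  perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
  fNull <- vapply(seq_len(nPerm), function(k) fStat(x[perms[k, ]]), numeric(1))
  pF <- if (is.infinite(fObs)) 1 / (nPerm + 1) else
    .permPValue(fObs, fNull, "greater")

  gl <- sort(unique(groups[keep]))
  pairs <- utils::combn(gl, 2L)
  nPairs <- ncol(pairs)
  ph <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   t = NA_real_, pSpin = NA_real_, pBonferroni = NA_real_)
  for (j in seq_len(nPairs)) {
    tObs <- tStat(x, pairs[1L, j], pairs[2L, j])
    tNull <- vapply(seq_len(nPerm), function(k)
      tStat(x[perms[k, ]], pairs[1L, j], pairs[2L, j]), numeric(1))
    ps <- if (is.infinite(tObs)) 1 / (nPerm + 1) else
      .permPValue(tObs, tNull, "two.sided")
    ph$t[j] <- tObs
    ph$pSpin[j] <- ps
    ph$pBonferroni[j] <- min(1, ps * nPairs)
  }
  list(F = fObs, pSpin = pF, postHoc = ph)
}

#' Within- versus between-type covariance test, spin null
#'
#' For each cortical type t: `Delta_t = mean(edges within t) - mean(edges
#' between t and other types)`, plus an overall Delta pooling all types
#' (mean same-type edge minus mean different-type edge). The null conjugates
#' the parcel assignment of the covariance matrix with spin permutations;
#' p-values are one-sided for `Delta > 0`. Types with fewer than 2 parcels
#' are undefined.
#'
#' @param cov a [CovarianceMatrix-class] or P x P matrix.
#' @param typeLabels per-parcel labels.
#' @param nPerm,seed,sphereCoords spin-null controls.
#' @return List with `perType` (data.frame: type, delta, pSpin) and
#'   `overall` (a [NullDistribution-class]).
#' @export
withinBetweenTypeTest <- function(cov, typeLabels, nPerm = 1000L, seed = 1L,
                                  sphereCoords = NULL) {
  m <- .asMatrix(cov)
  labs <- as.character(typeLabels)
  stopifnot(nrow(m) == length(labs))
  types <- sort(unique(labs))
  if (length(types) < 2L) stop("need at least 2 types")
  idx <- .lowerPairs(nrow(m))
  ev <- m[idx]
  same <- labs[idx[, 1L]] == labs[idx[, 2L]]

  deltas <- function(mm) {
    e <- mm[idx]
    sapply(types, function(t) {
      inT <- labs[idx[, 1L]] == t | labs[idx[, 2L]] == t
      w <- e[inT & same]
      b <- e[inT & !same]
      if (sum(!is.na(w)) < 1L || sum(!is.na(b)) < 1L) return(NA_real_)
      mean(w, na.rm = TRUE) - mean(b, na.rm = TRUE)
    })
  }
  overallDelta <- function(mm) {
    e <- mm[idx]
    mean(e[same], na.rm = TRUE) - mean(e[!same], na.rm = TRUE)
  }

  small <- types[table(factor(labs, levels = types)) < 2L]
  dObs <- deltas(m)
  dObs[types %in% small] <- NA_real_
  oObs <- overallDelta(m)

  perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
  dNull <- matrix(NA_real_, nPerm, length(types))
  oNull <- numeric(nPerm)
  for (k in seq_len(nPerm)) {
    pk <- perms[k, ]
    mk <- m[pk, pk]
    dNull[k, ] <- deltas(mk)
    oNull[k] <- overallDelta(mk)
  }
  perType <- data.frame(
    type = types,
    delta = dObs,
    pSpin = vapply(seq_along(types), function(j) {
      if (is.na(dObs[j])) return(NA_real_)
      .permPValue(dObs[j], dNull[, j], "greater")
    }, numeric(1)))
  list(perType = perType,
       overall = .newNullDistribution(oObs, oNull, "greater", seed))
}

#' Jensen-Shannon similarity of per-parcel value distributions
#'
#' Estimates, per parcel, the distribution of a per-vertex map (histogram
#' density on a shared global bin grid) and returns `1 - JSD` between every
#' parcel pair, with base-2 Jensen-Shannon divergence so similarity is
#' bounded in `[0, 1]`: 1 for identical distributions, 0 for disjoint
#' supports. Parcels with fewer than `minVertices` valid vertices are
#' undefined (NA row/column).
#'
#' @param x per-vertex numeric map.
#' @param parcellation a [Parcellation-class] or label vector.
#' @param nBins number of global histogram bins (default 64).
#' @param minVertices minimum valid vertices per parcel (default 5).
#' @return Symmetric P x P similarity matrix with unit diagonal.
#' @export
jsdSimilarity <- function(x, parcellation, nBins = 64L, minVertices = 5L) {
  labels <- if (is(parcellation, "Parcellation"))
    parcellation@labels else as.integer(parcellation)
  stopifnot(length(x) == length(labels))
  p <- max(labels)
  rng <- range(x, na.rm = TRUE)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  dens <- matrix(NA_real_, p, nBins)
  for (k in seq_len(p)) {
    v <- x[labels == k]
    v <- v[!is.na(v)]
    if (length(v) < minVertices) next
    h <- .clamp(findInterval(v, breaks, rightmost.closed = TRUE), 1L, nBins)
    dens[k, ] <- tabulate(h, nbins = nBins) / length(v)
  }
  out <- matrix(NA_real_, p, p)
  klTerm <- function(a, b) {
    pos <- a > 0
    sum(a[pos] * log2(a[pos] / b[pos]))
  }
  defined <- which(!is.na(dens[, 1L]))
  for (ii in defined) {
    for (jj in defined[defined >= ii]) {
      mMix <- (dens[ii, ] + dens[jj, ]) / 2
      jsd <- 0.5 * klTerm(dens[ii, ], mMix) + 0.5 * klTerm(dens[jj, ], mMix)
      out[ii, jj] <- out[jj, ii] <- 1 - jsd
    }
  }
  out[cbind(defined, defined)] <- 1
  out
}
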