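## Principal-axis embedding of covariance matrices (sparsify -> normalized
## angle affinity -> PCA / diffusion map / Laplacian eigenmap) and the
## discrete k-means alternative.

#' Row-wise sparsification of a similarity matrix
#'
#' Per row, keeps the `ceiling((1 - p) * n)` largest defined off-diagonal
#' entries (n = number of defined off-diagonal entries in that row) and sets
#' everything else, including NAs, to zero. Ties break deterministically to
#' the lower column index. The output is generally asymmetric; symmetry is
#' restored downstream by the affinity kernel.
#'
#' @param m numeric matrix ([CovarianceMatrix-class] accepted); may be
#'   rectangular (e.g. a fused P x 2P table).
#' @param p proportion of cells to zero per row, in `[0, 1)` (default 0.9).
#' @return Numeric matrix of the same shape.
#' @export
sparsifyRows <- function(m, p = 0.9) {
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  m <- .asMatrix(m)
  square <- nrow(m) == ncol(m)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    cand <- which(!is.na(row))
    if (square) cand <- setdiff(cand, i)
    keep <- ceiling((1 - p) * length(cand))
    if (keep > 0L) {
      ord <- cand[order(-row[cand], cand)]
      sel <- ord[seq_len(keep)]
      out[i, sel] <- row[sel]
    }
  }
  out
}

#' Normalized-angle affinity kernel
#'
#' `affinity(i, j) = 1 - arccos(cosine(row_i, row_j)) / pi`: 1 for parallel
#' rows, 0.5 for orthogonal rows, 0 for anti-parallel rows. Symmetric with a
#' unit diagonal. Cosines are clamped to `[-1, 1]` before `arccos`.
#'
#' @param m numeric matrix whose rows are (typically sparsified) similarity
#'   profiles; no row may be all-zero.
#' @return Symmetric P x P affinity matrix.
#' @export
normalizedAngleAffinity <- function(m) {
  m <- .asMatrix(m)
  rn <- sqrt(rowSums(m^2))
  if (any(rn == 0))
    stop("all-zero row(s) at parcel(s) ",
         paste(utils::head(which(rn == 0), 5L), collapse = ", "))
  cosv <- tcrossprod(m / rn)
  cosv <- .clamp(cosv, -1, 1)
  aff <- 1 - acos(cosv) / pi
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  dimnames(aff) <- list(rownames(m), rownames(m))
  aff
}

#' Gradient embedding of an affinity matrix
#'
#' With `method = "pca"` (the reference configuration), the affinity matrix
#' is column-centered and decomposed by SVD; loadings are the projections on
#' the top components and explained variance the component fractions of the
#' total centered variance. `"diffusion"` is a diffusion-map embedding with
#' anisotropic alpha = 0.5 normalization; `"laplacian"` a Laplacian
#' eigenmap of the affinity graph (for these two, the reported
#' `explainedVariance` is the normalized spectral weight of each retained
#' component, a descending analogue rather than a variance share).
#'
#' Component signs are arbitrary; if a `reference` matrix or vector is
#' supplied, each component is flipped to correlate positively with the
#' corresponding reference column.
#'
#' @param affinity symmetric P x P affinity matrix.
#' @param nComponents number of components to retain (default 10).
#' @param method `"pca"`, `"diffusion"` or `"laplacian"`.
#' @param reference optional P-vector or P x C matrix used for sign
#'   alignment.
#' @param sparsity the sparsification proportion recorded in the result
#'   (bookkeeping only).
#' @return A [GradientResult-class].
#' @seealso [covarianceGradients()] for the covariance-to-gradient pipeline.
#' @export
computeGradients <- function(affinity, nComponents = 10L,
                             method = c("pca", "diffusion", "laplacian"),
                             reference = NULL, sparsity = NA_real_) {
  method <- match.arg(method)
  p <- nrow(affinity)
  if (nComponents > p) stop("nComponents must not exceed the parcel count")
  if (max(abs(affinity - t(affinity))) > 1e-8)
    stop("affinity must be symmetric")

  if (method == "pca") {
    ac <- scale(affinity, center = TRUE, scale = FALSE)
    sv <- svd(ac, nu = 0L, nv = nComponents)
    loadings <- ac %*% sv$v
    ev <- (sv$d^2 / sum(sv$d^2))[seq_len(nComponents)]
  } else if (method == "diffusion") {
    d <- rowSums(affinity)
    w <- affinity / outer(sqrt(d), sqrt(d))   # alpha = 0.5 normalization
    d1 <- rowSums(w)
    s <- w / outer(sqrt(d1), sqrt(d1))
    s <- (s + t(s)) / 2
    eg <- eigen(s, symmetric = TRUE)
    psi <- eg$vectors / sqrt(d1)
    lam <- eg$values
    keep <- seq_len(nComponents) + 1L        # drop the trivial component
    loadings <- sweep(psi[, keep, drop = FALSE], 2L, lam[keep], "*")
    ev <- abs(lam[keep]) / sum(abs(lam[-1L]))
  } else {
    d <- rowSums(affinity)
    lsym <- diag(p) - affinity / outer(sqrt(d), sqrt(d))
    eg <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
    idx <- order(eg$values)[seq_len(nComponents) + 1L]
    loadings <- eg$vectors[, idx, drop = FALSE] / sqrt(d)
    spec <- 1 / pmax(eg$values[idx], .Machine$double.eps)
    ev <- spec / sum(spec)
  }

  flips <- rep(FALSE, nComponents)
  if (!is.null(reference)) {
    ref <- if (is.null(dim(reference))) matrix(reference, ncol = 1L) else reference
    for (k in seq_len(min(nComponents, ncol(ref)))) {
      r <- suppressWarnings(stats::cor(loadings[, k], ref[, k]))
      if (!is.na(r) && r < 0) {
        loadings[, k] <- -loadings[, k]
        flips[k] <- TRUE
      }
    }
  }
  rownames(loadings) <- rownames(affinity)
  colnames(loadings) <- paste0("G", seq_len(nComponents))
  new("GradientResult", loadings = loadings, explainedVariance = ev,
      method = method, sparsity = sparsity, signFlips = flips)
}

#' Covariance-to-gradient pipeline
#'
#' Convenience wrapper chaining [sparsifyRows()] (default p = 0.9),
#' [normalizedAngleAffinity()] and [computeGradients()].
#'
#' @param cov a [CovarianceMatrix-class] or numeric matrix.
#' @param p sparsification proportion.
#' @inheritParams computeGradients
#' @return A [GradientResult-class].
#' @export
covarianceGradients <- function(cov, p = 0.9, nComponents = 10L,
                                method = "pca", reference = NULL) {
  sp <- sparsifyRows(cov, p)
  aff <- normalizedAngleAffinity(sp)
  computeGradients(aff, nComponents = min(nComponents, nrow(aff) - 1L),
                   method = method, reference = reference, sparsity = p)
}

## k-means++ initial centers (deterministic given the RNG state).
.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  if (k == 1L) return(centers)
  for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering with elbow-based model selection
#'
#' Runs k-means (k-means++ initialization, `nRestarts` restarts, best
#' within-cluster sum of squares kept) for every candidate k, records the
#' distortion (mean within-cluster sum of squared distances), and selects
#' the elbow of the distortion curve by the maximum-distance-to-chord rule:
#' the candidate whose (k, distortion) point, after min-max normalization of
#' both axes, lies farthest from the straight line joining the curve's
#' endpoints.
#'
#' @param profiles numeric P x K feature matrix (e.g. relative laminar
#'   thickness profiles).
#' @param kCandidates integer vector of candidate cluster counts.
#' @param seed integer seed.
#' @param nRestarts k-means restarts per candidate (default 10).
#' @return A [ClusterResult-class].
#' @export
kmeansElbow <- function(profiles, kCandidates = 2:10, seed = 1L,
                        nRestarts = 10L) {
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  n <- nrow(profiles)
  if (n < max(kCandidates)) stop("candidate k must not exceed the row count")
  kCandidates <- sort(unique(as.integer(kCandidates)))
  set.seed(.splitSeed(seed, 11L))
  distortion <- stats::setNames(numeric(length(kCandidates)),
                                as.character(kCandidates))
  labelsByK <- vector("list", length(kCandidates))
  for (ki in seq_along(kCandidates)) {
    k <- kCandidates[ki]
    best <- NULL
    for (r in seq_len(nRestarts)) {
      centers <- .kmeansPP(profiles, k)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      fit <- suppressWarnings(
        stats::kmeans(profiles, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    distortion[ki] <- best$tot.withinss / n
    labelsByK[[ki]] <- best$cluster
  }
  chosen <- .elbowIndex(kCandidates, distortion)
  new("ClusterResult", labels = as.integer(labelsByK[[chosen]]),
      distortion = distortion, chosenK = kCandidates[chosen])
}

## Maximum-distance-to-chord elbow on a (k, distortion) curve.
.elbowIndex <- function(k, d) {
  if (length(k) == 1L) return(1L)
  kx <- (k - min(k)) / max(diff(range(k)), .Machine$double.eps)
  dy <- (d - min(d)) / max(diff(range(d)), .Machine$double.eps)
  x1 <- kx[1]; y1 <- dy[1]
  x2 <- kx[length(kx)]; y2 <- dy[length(dy)]
  num <- abs((y2 - y1) * kx - (x2 - x1) * dy + x2 * y1 - y2 * x1)
  which.max(num)
}
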