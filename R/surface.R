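## Mesh-level preprocessing: smoothing, curvature, parcel aggregation,
## geodesic distances, exclusion masking.

## Sparse V x V 0/1 disk membership matrix on the inflated coordinates.
## Row i marks all vertices within Euclidean distance radiusMm of vertex i
## (including i itself). Computed in row chunks to bound memory.
.diskMembership <- function(mesh, radiusMm, chunk = 512L) {
  cc <- companionCoords(mesh, "inflated")
  v <- nrow(cc)
  sq <- rowSums(cc^2)
  ii <- vector("list", ceiling(v / chunk))
  jj <- vector("list", length(ii))
  b <- 0L
  for (start in seq(1L, v, by = chunk)) {
    rows <- start:min(start + chunk - 1L, v)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(cc[rows, , drop = FALSE], cc)
    d2[cbind(seq_along(rows), rows)] <- 0   # self-distance, exact
    hit <- which(d2 <= radiusMm^2, arr.ind = TRUE)
    b <- b + 1L
    ii[[b]] <- rows[hit[, 1L]]
    jj[[b]] <- hit[, 2L]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1, dims = c(v, v))
}

#' Disk smoothing of per-vertex maps
#'
#' Replaces each valid vertex value by the unweighted mean over the "disk" of
#' valid vertices lying within `radiusMm` Euclidean distance of it on the
#' inflated surface (the vertex itself included). Invalid (NA) vertices are
#' excluded from every disk and remain NA in the output. This suppresses the
#' local, folding-driven component of laminar thickness while preserving the
#' broad spatial trends.
#'
#' @param x per-vertex numeric vector, V x k matrix, or a
#'   [LaminarThicknessMap-class] (smoothed layer-wise).
#' @param mesh a [SurfaceMesh-class] with an `"inflated"` companion.
#' @param radiusMm disk radius in mm (default 10). A radius smaller than the
#'   minimum inter-vertex spacing reduces every disk to the vertex itself, so
#'   smoothing becomes the identity.
#' @return Same shape/class as `x`.
#' @export
diskSmooth <- function(x, mesh, radiusMm = 10) {
  stopifnot(radiusMm > 0)
  if (!"inflated" %in% names(mesh@companions))
    stop("disk smoothing requires the 'inflated' companion coordinates")
  if (is(x, "LaminarThicknessMap")) {
    sm <- diskSmooth(x@thickness, mesh, radiusMm)
    return(new("LaminarThicknessMap", thickness = sm,
               validMask = x@validMask & rowSums(is.na(sm)) == 0L))
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(xm) != nVertices(mesh))
    stop("map length must equal the mesh vertex count")
  w <- .diskMembership(mesh, radiusMm)
  valid <- !is.na(xm)
  x0 <- xm
  x0[!valid] <- 0
  num <- as.matrix(w %*% x0)
  den <- as.matrix(w %*% (valid + 0))
  out <- num / den
  out[den == 0 | !valid] <- NA_real_
  dimnames(out) <- dimnames(xm)
  if (vec) out[, 1L] else out
}

#' Discrete mean curvature
#'
#' Mean curvature at every vertex from the cotangent-Laplacian mean-curvature
#' normal: `H = ||L x|| / (4 A)` with `A` the mixed Voronoi area, signed by
#' the orientation of the Laplacian vector against the outward vertex normal.
#' Positive curvature is convex-outward (gyral crowns on a folded cortex);
#' negative is concave (sulcal fundi). On a sphere of radius R the analytic
#' value is `1/R` everywhere.
#'
#' @param mesh a closed, consistently oriented [SurfaceMesh-class].
#' @return Numeric vector of per-vertex signed curvature (1/mm).
#' @export
meanCurvature <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@triangles
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p3 - p2   # edge opposite corner 1
  e2 <- p1 - p3
  e3 <- p2 - p1
  crossN <- cbind(e3[, 2] * (-e2[, 3]) - e3[, 3] * (-e2[, 2]),
                  e3[, 3] * (-e2[, 1]) - e3[, 1] * (-e2[, 3]),
                  e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  area2 <- sqrt(rowSums(crossN^2))        # 2 * triangle area
  if (any(area2 <= .Machine$double.eps * 100)) {
    bad <- which(area2 <= .Machine$double.eps * 100)[1]
    stop("degenerate (zero-area) triangle at row ", bad)
  }
  ## cotangents at each corner: cot = dot(adjacent edges) / (2 * area)
  cot1 <- rowSums((-e2) * e3) / area2
  cot2 <- rowSums((-e3) * e1) / area2
  cot3 <- rowSums((-e1) * e2) / area2

  nv <- nrow(v)
  lap <- matrix(0, nv, 3)
  addEdge <- function(lap, a, b, cot) {
    ## contribution cot * (x_a - x_b) to L_a and the mirror to L_b
    d <- v[a, , drop = FALSE] - v[b, , drop = FALSE]
    for (k in 1:3) {
      lap[, k] <- lap[, k] + unname(tapply2(cot * d[, k], a, nv)) -
        unname(tapply2(cot * d[, k], b, nv))
    }
    lap
  }
  tapply2 <- function(x, idx, n) {
    out <- numeric(n)
    acc <- rowsum(x, idx)
    out[as.integer(rownames(acc))] <- acc
    out
  }
  lap <- addEdge(lap, f[, 2], f[, 3], cot1)
  lap <- addEdge(lap, f[, 3], f[, 1], cot2)
  lap <- addEdge(lap, f[, 1], f[, 2], cot3)

  ## mixed Voronoi area (Meyer): Voronoi for acute triangles; area/2 at the
  ## obtuse corner and area/4 elsewhere otherwise
  l1 <- rowSums(e1^2); l2 <- rowSums(e2^2); l3 <- rowSums(e3^2)
  triArea <- area2 / 2
  obtuse1 <- cot1 < 0; obtuse2 <- cot2 < 0; obtuse3 <- cot3 < 0
  anyObtuse <- obtuse1 | obtuse2 | obtuse3
  a1 <- ifelse(anyObtuse, ifelse(obtuse1, triArea / 2, triArea / 4),
               (l2 * cot2 + l3 * cot3) / 8)
  a2 <- ifelse(anyObtuse, ifelse(obtuse2, triArea / 2, triArea / 4),
               (l3 * cot3 + l1 * cot1) / 8)
  a3 <- ifelse(anyObtuse, ifelse(obtuse3, triArea / 2, triArea / 4),
               (l1 * cot1 + l2 * cot2) / 8)
  area <- tapply2(a1, f[, 1], nv) + tapply2(a2, f[, 2], nv) +
    tapply2(a3, f[, 3], nv)

  ## outward vertex normal: area-weighted triangle normals (winding order)
  nrm <- matrix(0, nv, 3)
  for (k in 1:3) {
    nrm[, k] <- tapply2(crossN[, k], f[, 1], nv) +
      tapply2(crossN[, k], f[, 2], nv) + tapply2(crossN[, k], f[, 3], nv)
  }
  h <- sqrt(rowSums(lap^2)) / (4 * area)
  sgn <- sign(rowSums(lap * nrm))
  sgn[sgn == 0] <- 1
  h * sgn
}

#' Parcel centroid vertices
#'
#' The centroid of a parcel is its exact Euclidean medoid on the midsurface
#' coordinates: the member vertex with the lowest sum of Euclidean distances
#' to all other member vertices. Ties break to the lowest vertex index.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param labels per-vertex integer labels (0 = off-parcel) or a
#'   [Parcellation-class].
#' @return Integer vector of centroid vertex indices, one per parcel.
#' @export
parcelCentroids <- function(mesh, labels) {
  if (is(labels, "Parcellation")) labels <- labels@labels
  v <- mesh@vertices
  p <- max(labels)
  if (p < 1L) stop("no parcels: all labels are the off-parcel sentinel")
  out <- integer(p)
  for (k in seq_len(p)) {
    members <- which(labels == k)
    if (!length(members)) stop("parcel ", k, " is empty")
    if (length(members) == 1L) { out[k] <- members; next }
    cc <- v[members, , drop = FALSE]
    d <- as.matrix(stats::dist(cc))
    sums <- rowSums(d)
    out[k] <- members[which.min(sums)]  # which.min takes the first minimum
  }
  out
}

#' Geodesic distances between parcel centroids
#'
#' Shortest-path distances over the weighted mesh vertex graph between
#' centroid vertices. By default the edge graph is augmented with straight
#' chords to every vertex within `ring` mesh hops (weight = Euclidean
#' length), which removes most of the systematic overestimate that pure
#' edge-walk paths suffer from lattice-direction quantization; on a
#' subdivision-5 icosphere the augmented distances are within ~2% of the
#' analytic great-circle lengths.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param parcellation a [Parcellation-class] with centroids, or an integer
#'   vector of centroid vertex indices.
#' @param ring neighborhood order of the chord augmentation (1 = plain edge
#'   graph).
#' @return Symmetric P x P matrix of distances in mm (zero diagonal).
#' @export
geodesicParcelDistance <- function(mesh, parcellation, ring = 3L) {
  cv <- if (is(parcellation, "Parcellation"))
    parcellation@centroidVertex else as.integer(parcellation)
  if (anyNA(cv)) stop("parcellation has missing centroid vertices")
  g <- .meshGraph(mesh, ring = ring)
  d <- igraph::distances(g, v = cv, to = cv,
                         weights = igraph::E(g)$weight, algorithm = "dijkstra")
  if (any(!is.finite(d))) stop("mesh is disconnected: infinite geodesic distances")
  d <- (d + t(d)) / 2    # exact symmetry despite floating-point path order
  dimnames(d) <- list(seq_along(cv), seq_along(cv))
  d
}

#' Aggregate per-vertex maps into parcels
#'
#' Column-wise aggregation (median by default) of the valid vertex values
#' within each parcel. Parcels without any valid vertex get NA.
#'
#' @param x per-vertex numeric vector or V x k matrix (NA = invalid), or a
#'   [LaminarThicknessMap-class] / [RelativeLaminarMap-class] /
#'   [IntensityProfileMap-class].
#' @param parcellation a [Parcellation-class] (or integer label vector).
#' @param aggregator `"median"` or `"mean"`.
#' @return P x k numeric matrix (all parcels; rownames are parcel ids).
#' @export
parcellate <- function(x, parcellation, aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  fun <- if (aggregator == "median") stats::median else mean
  labels <- if (is(parcellation, "Parcellation"))
    parcellation@labels else as.integer(parcellation)
  if (is(x, "LaminarThicknessMap")) x <- ifelse(x@validMask, 1, NA) * x@thickness
  if (is(x, "RelativeLaminarMap")) x <- ifelse(x@validMask, 1, NA) * x@fractions
  if (is(x, "IntensityProfileMap")) x <- x@profile
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  if (nrow(xm) != length(labels))
    stop("map length must equal the labelled vertex count")
  p <- max(labels)
  out <- matrix(NA_real_, p, ncol(xm),
                dimnames = list(seq_len(p), colnames(xm)))
  grp <- split(seq_along(labels), labels)
  grp <- grp[names(grp) != "0"]
  for (nm in names(grp)) {
    rows <- grp[[nm]]
    out[as.integer(nm), ] <- apply(xm[rows, , drop = FALSE], 2L,
                                   fun, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Exclude parcels by cortical type
#'
#' Clears the inclusion mask for parcels whose cortical type is in
#' `excludedTypes` (default: the agranular and dysgranular types, whose layer
#' boundaries are poorly defined under a 6-layer model). Downstream matrix
#' builders operate only over included parcels.
#'
#' @param parcellation a [Parcellation-class].
#' @param typeLabels per-parcel type labels (character or factor).
#' @param excludedTypes character vector of type labels to exclude.
#' @return The updated [Parcellation-class].
#' @export
excludeRegions <- function(parcellation, typeLabels,
                           excludedTypes = c("agranular", "dysgranular")) {
  typeLabels <- as.character(typeLabels)
  if (length(typeLabels) != nParcels(parcellation))
    stop("typeLabels must have one entry per parcel")
  known <- corticalTypeLevels()
  unknown <- setdiff(unique(typeLabels), known)
  if (length(unknown))
    stop("unknown cortical type label(s): ", paste(unknown, collapse = ", "))
  mask <- parcellation@includedMask & !(typeLabels %in% excludedTypes)
  if (!any(mask)) stop("no included parcels remain after exclusion")
  new("Parcellation", labels = parcellation@labels, includedMask = mask,
      centroidVertex = parcellation@centroidVertex)
}

#' Ordered cortical type labels
#'
#' The six von-Economo-style cortical types in laminar-differentiation order.
#' @return Character vector of length 6.
#' @export
corticalTypeLevels <- function() {
  c("agranular", "dysgranular", "eulaminate1", "eulaminate2", "eulaminate3",
    "koniocortex")
}
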