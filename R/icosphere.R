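#' Generate an icosphere surface mesh
#'
#' Builds a sphere-topology triangulated mesh by recursive 4-way subdivision
#' of a regular icosahedron, with vertices projected back onto the sphere at
#' every level. The resulting mesh has `V = 10 * 4^s + 2` vertices at
#' subdivision level `s` and satisfies the Euler relation `V - E + F = 2`.
#'
#' Two companion coordinate sets are attached: `"sphere"` (unit-normalized
#' coordinates, consumed by spin permutations) and `"inflated"` (coordinates
#' rescaled to `inflatedRadius`, consumed by disk smoothing; for a synthetic
#' sphere the inflated surface is simply the sphere itself at the requested
#' radius).
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in mm (> 0).
#' @param inflatedRadius radius of the `"inflated"` companion (defaults to
#'   `radius`).
#' @return A [SurfaceMesh-class].
#' @examples
#' mesh <- makeIcosphere(2, radius = 100)
#' nVertices(mesh)  # 162
#' @export
makeIcosphere <- function(subdivisions, radius, inflatedRadius = radius) {
  stopifnot(length(subdivisions) == 1L, subdivisions >= 0,
            subdivisions == round(subdivisions),
            length(radius) == 1L, radius > 0, inflatedRadius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))

  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ## midpoint vertex for every unique edge, indexed past the old vertices
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(ekey)
    mids <- match(ekey, uk) + nv
    ue <- e[!duplicated(ekey), , drop = FALSE]
    newv <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    nt <- nrow(f)
    ab <- mids[seq_len(nt)]
    bc <- mids[nt + seq_len(nt)]
    ca <- mids[2L * nt + seq_len(nt)]
    f <- rbind(cbind(f[, 1], ab, ca),
               cbind(f[, 2], bc, ab),
               cbind(f[, 3], ca, bc),
               cbind(ab, bc, ca))
    v <- rbind(v, newv)
    v <- v / sqrt(rowSums(v^2))
  }

  unitV <- v
  dimnames(unitV) <- NULL
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  new("SurfaceMesh",
      vertices = unitV * radius,
      triangles = f,
      companions = list(sphere = unitV, inflated = unitV * inflatedRadius))
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return Integer E x 2 matrix with each undirected edge once (smaller index
#'   first).
#' @export
meshEdges <- function(mesh) {
  f <- mesh@triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e %*% c(1, nrow(mesh@vertices) + 1)), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

## Neighbor lists (1-ring) from the edge set.
.meshAdjacency <- function(mesh) {
  e <- meshEdges(mesh)
  v <- nrow(mesh@vertices)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(v)))
  unname(nb)
}

## Weighted graph over mesh vertices. ring = 1 gives the plain edge graph;
## ring > 1 additionally connects each vertex to its 2..ring-ring neighbors
## with straight-line (chord) weights, which suppresses the lattice-direction
## bias of polyline geodesics (see geodesicParcelDistance).
.meshGraph <- function(mesh, ring = 1L) {
  e <- meshEdges(mesh)
  if (ring > 1L) {
    adj <- .meshAdjacency(mesh)
    v <- nrow(mesh@vertices)
    extra <- vector("list", v)
    for (i in seq_len(v)) {
      ringSet <- adj[[i]]
      seen <- c(i, ringSet)
      hops <- integer(0)
      for (r in seq_len(ring - 1L)) {
        nxt <- setdiff(unique(unlist(adj[ringSet], use.names = FALSE)), seen)
        hops <- c(hops, nxt)
        seen <- c(seen, nxt)
        ringSet <- nxt
      }
      hops <- hops[hops > i]
      if (length(hops)) extra[[i]] <- cbind(i, hops)
    }
    e <- rbind(e, do.call(rbind, extra))
  }
  w <- sqrt(rowSums((mesh@vertices[e[, 1], , drop = FALSE] -
                     mesh@vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}
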