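#' Extract the numeric payload of a container
#'
#' @param x an ltcov object.
#' @return A numeric matrix or vector: thickness for
#'   [LaminarThicknessMap-class], fractions for [RelativeLaminarMap-class],
#'   intensities for [IntensityProfileMap-class], the parcel-by-parcel matrix
#'   for [CovarianceMatrix-class], and the surrogate matrix for
#'   [SurrogateEnsemble-class].
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "LaminarThicknessMap", function(x) x@thickness)
#' @rdname values
#' @export
setMethod("values", "RelativeLaminarMap", function(x) x@fractions)
#' @rdname values
#' @export
setMethod("values", "IntensityProfileMap", function(x) x@profile)
#' @rdname values
#' @export
setMethod("values", "CovarianceMatrix", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "SurrogateEnsemble", function(x) x@surrogates)

#' Number of vertices of a mesh-like object
#' @param x a [SurfaceMesh-class] or [Parcellation-class].
#' @return integer.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
#' @rdname nVertices
#' @export
setMethod("nVertices", "Parcellation", function(x) length(x@labels))

#' Number of parcels of a parcellation
#' @param x a [Parcellation-class].
#' @return integer (all parcels, included or not).
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))
#' @rdname nParcels
#' @export
setMethod("nParcels", "Parcellation", function(x) length(x@includedMask))

#' Mesh coordinate accessors
#'
#' `meshVertices` returns the midsurface coordinates, `meshTriangles` the
#' triangle index matrix, and `companionCoords` a named companion coordinate
#' set such as `"sphere"` or `"inflated"`.
#'
#' @param x a [SurfaceMesh-class].
#' @param name companion set name.
#' @return numeric matrix.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname meshVertices
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname meshVertices
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))
#' @rdname meshVertices
#' @export
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)

#' @rdname meshVertices
#' @export
setGeneric("companionCoords", function(x, name) standardGeneric("companionCoords"))
#' @rdname meshVertices
#' @export
setMethod("companionCoords", "SurfaceMesh", function(x, name) {
  if (!name %in% names(x@companions))
    stop("mesh has no companion coordinate set '", name, "'")
  x@companions[[name]]
})

#' Parcellation accessors
#'
#' `parcelLabels` returns the per-vertex labels (0 = off-parcel),
#' `includedParcels` the indices of included parcels, and `centroidVertices`
#' the per-parcel medoid vertex indices.
#'
#' @param x a [Parcellation-class].
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))
#' @rdname parcelLabels
#' @export
setMethod("parcelLabels", "Parcellation", function(x) x@labels)

#' @rdname parcelLabels
#' @export
setGeneric("includedParcels", function(x) standardGeneric("includedParcels"))
#' @rdname parcelLabels
#' @export
setMethod("includedParcels", "Parcellation", function(x) which(x@includedMask))

#' @rdname parcelLabels
#' @export
setGeneric("centroidVertices", function(x) standardGeneric("centroidVertices"))
#' @rdname parcelLabels
#' @export
setMethod("centroidVertices", "Parcellation", function(x) x@centroidVertex)

#' Gradient result accessors
#' @param x a [GradientResult-class].
#' @export
setGeneric("gradientLoadings", function(x) standardGeneric("gradientLoadings"))
#' @rdname gradientLoadings
#' @export
setMethod("gradientLoadings", "GradientResult", function(x) x@loadings)

#' @rdname gradientLoadings
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname gradientLoadings
#' @export
setMethod("explainedVariance", "GradientResult", function(x) x@explainedVariance)

#' Null-distribution accessors
#' @param x a [NullDistribution-class] or [FitResult-class].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname pValue
#' @export
setMethod("pValue", "NullDistribution", function(x) x@pValue)
#' @rdname pValue
#' @export
setMethod("pValue", "FitResult", function(x) x@pValue)

#' @rdname pValue
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname pValue
#' @export
setMethod("observedStat", "NullDistribution", function(x) x@observed)

#' @rdname pValue
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))
#' @rdname pValue
#' @export
setMethod("nullStats", "NullDistribution", function(x) x@nulls)

## show methods ---------------------------------------------------------------

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles; companions: %s\n",
              nrow(object@vertices), nrow(object@triangles),
              paste(names(object@companions), collapse = ", ")))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d parcels (%d included) on %d vertices\n",
              nParcels(object), sum(object@includedMask),
              length(object@labels)))
})

setMethod("show", "LaminarThicknessMap", function(object) {
  cat(sprintf("LaminarThicknessMap: %d vertices (%d valid), 6 layers\n",
              nrow(object@thickness), sum(object@validMask)))
})

setMethod("show", "RelativeLaminarMap", function(object) {
  cat(sprintf("RelativeLaminarMap: %d rows (%d valid), 6 layers\n",
              nrow(object@fractions), sum(object@validMask)))
})

setMethod("show", "IntensityProfileMap", function(object) {
  cat(sprintf("IntensityProfileMap: %d vertices, %d depth samples\n",
              nrow(object@profile), ncol(object@profile)))
})

setMethod("show", "CovarianceMatrix", function(object) {
  cat(sprintf("CovarianceMatrix (%s%s): %d x %d parcels\n",
              object@kind, if (object@fisherZ) ", Fisher z" else "",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "GradientResult", function(object) {
  cat(sprintf("GradientResult (%s): %d parcels, %d components; EV1 = %.1f%%\n",
              object@method, nrow(object@loadings), ncol(object@loadings),
              100 * object@explainedVariance[1]))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: chosen k = %d (candidates %s)\n",
              object@chosenK,
              paste(names(object@distortion), collapse = ", ")))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: observed = %.4g, p = %.4g (%s, %d permutations)\n",
              object@observed, object@pValue, object@tail, object@nPerm))
})

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf("SurrogateEnsemble: %d surrogates of a %d-parcel map\n",
              nrow(object@surrogates), ncol(object@surrogates)))
})

setMethod("show", "FitResult", function(object) {
  co <- paste(sprintf("%s = %.4g", names(object@coefficients),
                      object@coefficients), collapse = ", ")
  cat(sprintf("FitResult (%s): %s; %s = %.4g; p = %s; n = %d\n",
              object@model, co, object@gofType, object@gof,
              format(object@pValue, digits = 3), object@nEdges))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed %d, %d parcels, subdivision %d ",
                     "icosphere (radius %.0f mm)\n"),
              object@seed, object@nParcels, object@meshSubdivisions,
              object@radius))
})
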