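## File I/O: GIFTI surface/metric/label files (ASCII-encoded data arrays)
## and CSV matrices/tables with parcel-id headers.

.giftiDataArray <- function(doc, values, intent, dataType, dims, name = NULL) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent,
    DataType = dataType,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII",
    Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (k in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", k - 1L), as.character(dims[k]))
  if (!is.null(name)) {
    md <- xml2::xml_add_child(da, "MetaData")
    mdEntry <- xml2::xml_add_child(md, "MD")
    xml2::xml_add_child(mdEntry, "Name", "Name")
    xml2::xml_add_child(mdEntry, "Value", name)
  }
  txt <- if (is.integer(values)) paste(as.vector(t(values)), collapse = " ")
         else paste(formatC(as.vector(t(values)), format = "g", digits = 17),
                    collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

.giftiParseArrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop("malformed GIFTI file (no DataArray): ", path)
  lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("unsupported GIFTI encoding '", enc, "' in ", path,
           " (only ASCII is supported)")
    ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(k)
      as.integer(xml2::xml_attr(da, paste0("Dim", k))), integer(1))
    raw <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- scan(text = raw, quiet = TRUE)
    if (length(vals) != prod(dims))
      stop("GIFTI data length ", length(vals), " does not match dims ",
           paste(dims, collapse = "x"), " in ", path)
    m <- if (ndim == 2L)
      matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE) else vals
    nameNode <- xml2::xml_find_first(
      da, "./MetaData/MD[Name='Name']/Value")
    list(intent = xml2::xml_attr(da, "Intent"),
         dataType = xml2::xml_attr(da, "DataType"),
         values = m,
         name = if (inherits(nameNode, "xml_missing")) NA_character_
                else xml2::xml_text(nameNode),
         node = da)
  })
}

#' Write / read a GIFTI surface file
#'
#' The midsurface is stored as the standard POINTSET + TRIANGLE pair
#' (triangles 0-based on disk); companion coordinate sets are stored as
#' additional named POINTSET arrays in the same file, so a full
#' [SurfaceMesh-class] round-trips through one `.surf.gii`. Data arrays are
#' ASCII-encoded at full double precision.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file (conventionally `.surf.gii`).
#' @return `writeSurfaceGifti` returns `path` invisibly; `readSurfaceGifti`
#'   returns a [SurfaceMesh-class].
#' @export
writeSurfaceGifti <- function(mesh, path) {
  nArr <- 2L + length(mesh@companions)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(nArr))
  .giftiDataArray(doc, mesh@vertices, "NIFTI_INTENT_POINTSET",
                  "NIFTI_TYPE_FLOAT32", dim(mesh@vertices),
                  name = "midsurface")
  .giftiDataArray(doc, mesh@triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32", dim(mesh@triangles))
  for (nm in names(mesh@companions))
    .giftiDataArray(doc, mesh@companions[[nm]], "NIFTI_INTENT_POINTSET",
                    "NIFTI_TYPE_FLOAT32", dim(mesh@companions[[nm]]),
                    name = nm)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeSurfaceGifti
#' @export
readSurfaceGifti <- function(path) {
  arrays <- .giftiParseArrays(path)
  pts <- arrays[vapply(arrays, function(a)
    a$intent == "NIFTI_INTENT_POINTSET", logical(1))]
  tri <- arrays[vapply(arrays, function(a)
    a$intent == "NIFTI_INTENT_TRIANGLE", logical(1))]
  if (!length(pts) || !length(tri))
    stop("GIFTI surface must contain POINTSET and TRIANGLE arrays: ", path)
  names(pts) <- vapply(pts, function(a) a$name, character(1))
  main <- if ("midsurface" %in% names(pts)) pts[["midsurface"]] else pts[[1L]]
  comps <- pts[setdiff(names(pts), c("midsurface", NA))]
  comps <- comps[!is.na(names(comps))]
  triangles <- tri[[1L]]$values + 1L
  storage.mode(triangles) <- "integer"
  new("SurfaceMesh", vertices = main$values, triangles = triangles,
      companions = lapply(comps, function(a) a$values))
}

#' Write / read a GIFTI metric (per-vertex scalar) file
#'
#' One data array per column; NA is serialized as NaN. When `mesh` is
#' supplied on read, a vertex-count mismatch is an error.
#'
#' @param x per-vertex numeric vector or V x k matrix.
#' @param path output file (conventionally `.func.gii` / `.shape.gii`).
#' @param mesh optional [SurfaceMesh-class] for vertex-count validation.
#' @return `writeMetricGifti` returns `path` invisibly; `readMetricGifti`
#'   returns a numeric matrix (V x k).
#' @export
writeMetricGifti <- function(x, path) {
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(xm)))
  for (k in seq_len(ncol(xm)))
    .giftiDataArray(doc, xm[, k], "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                    nrow(xm), name = colnames(xm)[k])
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeMetricGifti
#' @export
readMetricGifti <- function(path, mesh = NULL) {
  arrays <- .giftiParseArrays(path)
  cols <- lapply(arrays, function(a) as.vector(a$values))
  n <- unique(lengths(cols))
  if (length(n) != 1L)
    stop("metric arrays have inconsistent lengths in ", path)
  if (!is.null(mesh) && n != nVertices(mesh))
    stop("metric has ", n, " vertices but the surface has ",
         nVertices(mesh), ": ", path)
  out <- do.call(cbind, cols)
  nms <- vapply(arrays, function(a) a$name, character(1))
  if (!all(is.na(nms))) colnames(out) <- nms
  out
}

#' Write / read a GIFTI label (parcellation) file
#'
#' Stores per-vertex integer labels with a label table (key 0 reserved for
#' the off-parcel sentinel `"???"`).
#'
#' @param labels per-vertex integer labels (0 = off-parcel) or a
#'   [Parcellation-class].
#' @param path output file (conventionally `.label.gii`).
#' @param names optional parcel names (defaults to `parcel_<k>`).
#' @param mesh optional [SurfaceMesh-class] for vertex-count validation.
#' @return `writeLabelGifti` returns `path` invisibly; `readLabelGifti`
#'   returns an integer label vector with a `labelTable` attribute.
#' @export
writeLabelGifti <- function(labels, path, names = NULL) {
  if (is(labels, "Parcellation")) labels <- labels@labels
  p <- max(labels)
  if (is.null(names)) names <- paste0("parcel_", seq_len(p))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  xml2::xml_add_child(lt, "Label", "???", Key = "0")
  for (k in seq_len(p))
    xml2::xml_add_child(lt, "Label", names[k], Key = as.character(k))
  .giftiDataArray(doc, as.integer(labels), "NIFTI_INTENT_LABEL",
                  "NIFTI_TYPE_INT32", length(labels))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeLabelGifti
#' @export
readLabelGifti <- function(path, mesh = NULL) {
  arrays <- .giftiParseArrays(path)
  lab <- arrays[vapply(arrays, function(a)
    a$intent == "NIFTI_INTENT_LABEL", logical(1))]
  if (!length(lab)) stop("no label array in ", path)
  out <- as.integer(lab[[1L]]$values)
  if (!is.null(mesh) && length(out) != nVertices(mesh))
    stop("labels have ", length(out), " vertices but the surface has ",
         nVertices(mesh), ": ", path)
  doc <- xml2::read_xml(path)
  lt <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  if (length(lt)) {
    attr(out, "labelTable") <- stats::setNames(
      xml2::xml_text(lt), xml2::xml_attr(lt, "Key"))
  }
  out
}

#' Write / read a parcel matrix as CSV
#'
#' Matrices are stored with parcel-id header row and column; undefined
#' entries are `NA`. `readMatrixCsv` refuses files without a header row.
#'
#' @param m numeric matrix ([CovarianceMatrix-class] accepted).
#' @param path file path.
#' @return `writeMatrixCsv` returns `path` invisibly; `readMatrixCsv`
#'   returns a numeric matrix with dimnames.
#' @export
writeMatrixCsv <- function(m, path) {
  m <- .asMatrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  df <- data.frame(parcel = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
readMatrixCsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- gsub('^"|"$', "", header)
  if (!identical(header[1L], "parcel"))
    stop("matrix CSV must carry a parcel-id header (first cell 'parcel'): ",
         path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
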