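## End-to-end pipeline driver: exclude -> smooth -> normalize -> parcellate
## -> LTC -> gradients (+ hierarchy, connectivity models, optional nulls),
## with all intermediates written to disk and a provenance log.

#' Run the laminar covariance pipeline
#'
#' Executes the full analysis in the canonical order: exclusion of
#' a-/dysgranular parcels, disk smoothing of the absolute layer thicknesses,
#' normalization to relative thickness, median parcellation, covariance
#' matrix construction, and gradient embedding; optionally followed by the
#' hierarchy and connectivity models and spatially constrained null tests.
#' Smoothing always precedes normalization (smoothing relative instead of
#' absolute thickness is a different, unsupported analysis and is rejected).
#'
#' Either supply a [SimulationConfig-class] (synthetic mode) or a named list
#' of file `paths` with elements `surface`, `thickness`, `labels` and
#' optionally `types`, `ec`, `sc`, `fc` (real-data mode; GIFTI/CSV as
#' written by the package writers).
#'
#' All numeric outputs are written under `outDir` (CSV for matrices and
#' tables, GIFTI for per-vertex maps) together with `provenance.json`
#' recording the configuration, seeds and package version. Reruns with an
#' identical configuration are bit-identical.
#'
#' @param simConfig a [SimulationConfig-class], or NULL when `paths` given.
#' @param paths named list of input files (real-data mode).
#' @param outDir output directory (created if missing); NULL disables
#'   writing.
#' @param smoothingRadius disk radius in mm (default 10; 0 skips smoothing).
#' @param metric covariance metric passed to [buildLTC()].
#' @param sparsity row-sparsification proportion (default 0.9).
#' @param embeddingMethod gradient method (default `"pca"`).
#' @param nComponents retained components (default 10).
#' @param excludedTypes cortical types to exclude.
#' @param runConnectivity fit the hierarchy/SC/FC models (synthetic mode).
#' @param nPerm permutations for the null tests (0 = skip nulls).
#' @param seed integer seed for the null tests.
#' @return Invisibly, a list with the intermediates: `parcellation`,
#'   `types`, `smoothed`, `relative`, `parcelProfiles`, `ltc`, `gradients`,
#'   and (when enabled) `hierarchy`, `fits`, `nulls`, plus a `log`
#'   data.frame of stage records.
#' @export
runPipeline <- function(simConfig = simulationConfig(), paths = NULL,
                        outDir = NULL, smoothingRadius = 10,
                        metric = "partial", sparsity = 0.9,
                        embeddingMethod = "pca", nComponents = 10L,
                        excludedTypes = c("agranular", "dysgranular"),
                        runConnectivity = TRUE, nPerm = 0L, seed = 1L) {
  t0 <- Sys.time()
  logRows <- list()
  note <- function(stage, detail) {
    logRows[[length(logRows) + 1L]] <<- data.frame(
      stage = stage, detail = detail,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message(sprintf("[%s] %s", stage, detail))
  }

  if (is.null(paths)) {
    note("simulate", sprintf("synthetic cortex, seed %d", simConfig@seed))
    sim <- simulateCortex(simConfig)
    mesh <- sim$mesh; parc <- sim$parcellation
    thickness <- sim$thickness
    types <- sim$types
  } else {
    note("load", "reading surface, thickness and labels")
    mesh <- readSurfaceGifti(paths$surface)
    th <- readMetricGifti(paths$thickness, mesh = mesh)
    if (ncol(th) != 6L) stop("thickness metric must have 6 layers")
    labels <- readLabelGifti(paths$labels, mesh = mesh)
    labels <- as.integer(labels)
    parc <- new("Parcellation", labels = labels,
                includedMask = rep(TRUE, max(labels)),
                centroidVertex = parcelCentroids(mesh, labels))
    mask <- rowSums(is.na(th)) == 0L & rowSums(th <= 0, na.rm = TRUE) == 0L
    th[!mask, ] <- NA_real_
    thickness <- new("LaminarThicknessMap", thickness = th, validMask = mask)
    types <- if (!is.null(paths$types)) {
      tt <- utils::read.csv(paths$types)
      factor(tt$type, levels = corticalTypeLevels())
    } else NULL
    sim <- list(mesh = mesh, parcellation = parc)
  }

  ## 1. exclusion: drop a-/dysgranular parcels, invalidate their vertices
  if (!is.null(types)) {
    parc <- excludeRegions(parc, types, excludedTypes)
    note("exclude", sprintf("%d / %d parcels included",
                            length(includedParcels(parc)), nParcels(parc)))
    off <- !(parc@labels %in% includedParcels(parc))
    th <- thickness@thickness
    th[off, ] <- NA_real_
    thickness <- new("LaminarThicknessMap", thickness = th,
                     validMask = thickness@validMask & !off)
  }

  ## 2. smoothing of absolute laminar thickness
  smoothed <- if (smoothingRadius > 0) {
    note("smooth", sprintf("disk radius %g mm", smoothingRadius))
    diskSmooth(thickness, mesh, smoothingRadius)
  } else {
    note("smooth", "skipped (radius 0)")
    thickness
  }

  ## 3. normalization to relative thickness, 4. parcellation (median)
  rel <- relativeThickness(smoothed)
  note("normalize", "relative laminar thickness")
  parcelProfiles <- parcellate(rel, parc)
  inc <- includedParcels(parc)
  parcelProfiles <- parcelProfiles[inc, , drop = FALSE]
  note("parcellate", sprintf("%d parcel profiles (median)", nrow(parcelProfiles)))

  ## 5. covariance, 6. gradients
  ltc <- buildLTC(parcelProfiles, metric = metric)
  note("ltc", sprintf("%s covariance over %d parcels", metric, nrow(parcelProfiles)))
  grad <- covarianceGradients(ltc, p = sparsity, nComponents = nComponents,
                              method = embeddingMethod)
  note("gradient", sprintf("%s embedding, EV1 = %.1f%%", embeddingMethod,
                           100 * explainedVariance(grad)[1]))

  result <- list(parcellation = parc, types = types, smoothed = smoothed,
                 relative = rel, parcelProfiles = parcelProfiles, ltc = ltc,
                 gradients = grad)
  if (!is.null(sim$axis)) result$plantedAxis <- parcellate(sim$axis, parc)[inc, 1L]
  if (!is.null(sim$gd)) result$gd <- sim$gd[inc, inc, drop = FALSE]

  if (runConnectivity && !is.null(sim$ec)) {
    hier <- asymmetryHierarchy(sim$ec[inc, inc, drop = FALSE])
    ed <- buildEdgeTable(ltc = ltc@values,
                         gd = sim$gd[inc, inc, drop = FALSE],
                         sc = sim$sc[inc, inc, drop = FALSE],
                         fc = sim$fc[inc, inc, drop = FALSE])
    fits <- list(
      scLtc = scLikelihoodModel(ed$sc, list(ltc = ed$ltc)),
      scGd = scLikelihoodModel(ed$sc, list(gd = ed$gd)),
      fcGd = exponentialDistanceFit(ed$fc, ed$gd),
      fcLtc = edgeCorrelation(ed$ltc, ed$fc))
    note("connectivity", sprintf(
      "SC~LTC pseudo-R2 = %.3f; FC~GD R2 = %.3f",
      fits$scLtc@gof, fits$fcGd@gof))
    result$hierarchy <- hier
    result$edges <- ed
    result$fits <- fits
  }

  if (nPerm > 0L) {
    sphere <- companionCoords(mesh, "sphere")[parc@centroidVertex[inc], ]
    g1 <- gradientLoadings(grad)[, 1L]
    nulls <- list()
    if (!is.null(result$plantedAxis)) {
      nulls$g1Axis <- correlationTest(
        g1, result$plantedAxis, nullSource = "variogram", nPerm = nPerm,
        seed = seed, dist = result$gd)
    }
    if (!is.null(result$hierarchy)) {
      nulls$g1Hierarchy <- correlationTest(
        g1, result$hierarchy$hierarchy, nullSource = "spin", nPerm = nPerm,
        seed = seed, sphereCoords = sphere)
    }
    note("null", sprintf("%d tests at %d permutations", length(nulls), nPerm))
    result$nulls <- nulls
  }

  result$log <- do.call(rbind, logRows)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMatrixCsv(ltc, file.path(outDir, "ltc.csv"))
    lt <- gradientLoadings(grad)
    utils::write.csv(data.frame(parcel = rownames(lt), lt),
                     file.path(outDir, "gradients.csv"), row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(explainedVariance(grad)),
                                fraction = explainedVariance(grad)),
                     file.path(outDir, "explained_variance.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(parcel = seq_len(nParcels(parc)),
                                included = parc@includedMask,
                                type = if (is.null(types)) NA else
                                  as.character(types)),
                     file.path(outDir, "parcels.csv"), row.names = FALSE)
    if (!is.null(result$gd))
      writeMatrixCsv(result$gd, file.path(outDir, "gd.csv"))
    prov <- list(
      package = "ltcov",
      version = as.character(utils::packageVersion("ltcov")),
      created = format(t0, "%Y-%m-%dT%H:%M:%S"),
      seed = seed, nPerm = nPerm,
      smoothingRadius = smoothingRadius, metric = metric,
      sparsity = sparsity, embeddingMethod = embeddingMethod,
      simConfig = if (is.null(paths)) .configAsList(simConfig) else NULL,
      paths = paths,
      stages = result$log$stage)
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    note("write", outDir)
  }
  invisible(result)
}

.configAsList <- function(config) {
  nm <- methods::slotNames(config)
  stats::setNames(lapply(nm, function(s) methods::slot(config, s)), nm)
}

#' Write a simulated cortex to disk
#'
#' Serializes every object of a [simulateCortex()] result: GIFTI surface,
#' metric and label files for the mesh and per-vertex maps, CSV for the
#' parcel-level matrices and tables, and a JSON sidecar with the
#' configuration.
#'
#' @param sim result of [simulateCortex()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSurfaceGifti(sim$mesh, file.path(dir, "cortex.surf.gii"))
  th <- sim$thickness@thickness
  colnames(th) <- paste0("layer", 1:6)
  writeMetricGifti(th, file.path(dir, "thickness.func.gii"))
  writeMetricGifti(cbind(axis = sim$axis, curvature = sim$curvature),
                   file.path(dir, "maps.func.gii"))
  writeMetricGifti(sim$profiles@profile, file.path(dir, "profiles.func.gii"))
  writeLabelGifti(sim$parcellation, file.path(dir, "parcellation.label.gii"))
  utils::write.csv(data.frame(parcel = seq_len(nParcels(sim$parcellation)),
                              type = as.character(sim$types),
                              hierarchy = sim$hierarchy),
                   file.path(dir, "parcels.csv"), row.names = FALSE)
  writeMatrixCsv(sim$gd, file.path(dir, "gd.csv"))
  writeMatrixCsv(sim$ec, file.path(dir, "ec.csv"))
  writeMatrixCsv(sim$sc, file.path(dir, "sc.csv"))
  writeMatrixCsv(sim$fc, file.path(dir, "fc.csv"))
  jsonlite::write_json(.configAsList(sim$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
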