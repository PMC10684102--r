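## Hierarchy from directed connectivity; distance and similarity models of
## SC likelihood and FC strength.

#' Asymmetry-based hierarchy from directed connectivity
#'
#' Converts the matrix to unsigned weights and scores each node by its
#' weighted out-degree minus in-degree (diagonal excluded): nodes whose
#' efferent influence exceeds their afferent influence sit higher in the
#' hierarchy. The scores sum to zero exactly (every edge contributes `+|w|`
#' to one node and `-|w|` to the other).
#'
#' @param ec square P x P directed connectivity matrix; entry (i, j) is the
#'   influence of source i on target j. The diagonal is ignored.
#' @return List with `hierarchy`, `outDegree` and `inDegree` (numeric
#'   P-vectors).
#' @export
asymmetryHierarchy <- function(ec) {
  if (!.isSquare(ec)) stop("connectivity matrix must be square")
  a <- abs(ec)
  diag(a) <- 0
  a[is.na(a)] <- 0
  out <- rowSums(a)
  inn <- colSums(a)
  list(hierarchy = out - inn, outDegree = out, inDegree = inn)
}

#' Exponential distance fit
#'
#' Nonlinear least squares for `y = a * exp(-d / lambda) + c`, the standard
#' description of how edge similarity or connectivity strength decays with
#' geodesic distance. Initialized at `a = range(y)`, `lambda = median(d)`,
#' `c = min(y)`; on non-convergence the fit is retried from a small set of
#' deterministically perturbed starts. Goodness of fit is
#' `R^2 = 1 - SS_res / SS_tot` on the original scale.
#'
#' If `y` and `d` are P x P matrices and `sphereCoords` is supplied, a spin
#' permutation p-value for R^2 is computed by conjugate-permuting `y` and
#' refitting (`nPerm` spins).
#'
#' @param y edge values: numeric vector or P x P matrix
#'   ([CovarianceMatrix-class] accepted).
#' @param d geodesic distances, same shape as `y`; must be positive.
#' @param sphereCoords optional P x 3 parcel centroid coordinates on the
#'   sphere (enables the spin null; matrices only).
#' @param nPerm,seed spin-null controls.
#' @return A [FitResult-class]; `extra` carries `fitted` values and, for
#'   matrix input, the defined-edge index.
#' @export
exponentialDistanceFit <- function(y, d, sphereCoords = NULL, nPerm = 0L,
                                   seed = 1L) {
  yM <- .asMatrix(y)
  isMat <- is.matrix(yM)
  if (isMat) {
    ed <- .sharedEdges(y = yM, d = .asMatrix(d))
    yv <- ed$y; dv <- ed$d
  } else {
    keep <- stats::complete.cases(cbind(yM, d))
    yv <- yM[keep]; dv <- d[keep]
  }
  if (length(yv) < 10L) stop("need at least 10 defined edges")
  if (any(dv <= 0)) stop("distances must be positive")
  fit <- .expFit(yv, dv)
  r2 <- fit$r2

  p <- NA_real_
  nulls <- numeric(0)
  if (nPerm > 0L) {
    if (!isMat || is.null(sphereCoords))
      stop("the spin null requires matrix input and sphereCoords")
    perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
    nulls <- vapply(seq_len(nPerm), function(k) {
      pk <- perms[k, ]
      ys <- yM[pk, pk, drop = FALSE]
      edk <- .sharedEdges(y = ys, d = .asMatrix(d))
      out <- tryCatch(.expFit(edk$y, edk$d)$r2, error = function(e) NA_real_)
      out
    }, numeric(1))
    p <- .permPValue(r2, nulls, "greater")
  }
  new("FitResult", model = "exponential", coefficients = fit$coef,
      gof = r2, gofType = "r.squared", pValue = p,
      nEdges = length(yv),
      extra = list(fitted = fit$fitted, nulls = nulls))
}

.expFit <- function(yv, dv) {
  if (stats::sd(yv) == 0) stop("degenerate fit: constant response")
  starts <- list(
    c(a = diff(range(yv)), lambda = stats::median(dv), c0 = min(yv)),
    c(a = 2 * diff(range(yv)), lambda = stats::median(dv) / 4, c0 = mean(yv)),
    c(a = stats::sd(yv), lambda = stats::median(dv) * 2, c0 = min(yv)),
    c(a = -diff(range(yv)), lambda = stats::median(dv), c0 = max(yv)))
  last <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yv ~ a * exp(-dv / lambda) + c0,
                        start = as.list(s),
                        lower = c(-Inf, 1e-8, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      co <- stats::coef(fit)
      fitted <- co[["a"]] * exp(-dv / co[["lambda"]]) + co[["c0"]]
      ssRes <- sum((yv - fitted)^2)
      ssTot <- sum((yv - mean(yv))^2)
      return(list(coef = c(a = co[["a"]], lambda = co[["lambda"]],
                           c = co[["c0"]]),
                  fitted = fitted, r2 = 1 - ssRes / ssTot))
    }
    last <- fit
  }
  stop("exponential fit did not converge after bounded restarts: ",
       conditionMessage(last))
}

#' Regress geodesic distance out of a covariance matrix
#'
#' Fits [exponentialDistanceFit()] on the defined lower-triangle edges and
#' places the residuals `y - yhat` back into a symmetric matrix; undefined
#' entries (including the diagonal) are preserved as NA.
#'
#' @param cov a [CovarianceMatrix-class] or P x P matrix.
#' @param gd P x P geodesic distance matrix.
#' @return Same class as `cov`, with distance-residualized values.
#' @export
residualizeDistance <- function(cov, gd) {
  m <- .asMatrix(cov)
  ed <- .sharedEdges(y = m, d = .asMatrix(gd))
  fit <- .expFit(ed$y, ed$d)
  res <- .edgesToMatrix(ed$i, ed$j, ed$y - fit$fitted, nrow(m), dimnames(m))
  if (is(cov, "CovarianceMatrix"))
    new("CovarianceMatrix", values = res, kind = cov@kind, fisherZ = FALSE)
  else res
}

#' Logistic model of connection likelihood
#'
#' Maximum-likelihood logistic regression of a binarized structural
#' connectivity outcome on one or more edge predictors (each standardized
#' internally), with intercept. Goodness of fit is McFadden's pseudo
#' R-squared `1 - l_model / l_null` by default (Cox-Snell selectable). With
#' `sphereCoords` and `nPerm`, a spin permutation p-value is computed by
#' conjugate-permuting the first predictor matrix and refitting.
#'
#' @param sc binary outcome: P x P matrix or edge vector.
#' @param predictors named list of predictors (same shape as `sc`), or a
#'   single vector/matrix.
#' @param pseudoR2 `"mcfadden"` or `"coxsnell"`.
#' @param sphereCoords,nPerm,seed spin-null controls (matrix input only).
#' @return A [FitResult-class] with standardized coefficients.
#' @export
scLikelihoodModel <- function(sc, predictors, pseudoR2 = c("mcfadden", "coxsnell"),
                              sphereCoords = NULL, nPerm = 0L, seed = 1L) {
  pseudoR2 <- match.arg(pseudoR2)
  if (!is.list(predictors)) predictors <- list(x = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("x", seq_along(predictors))
  scM <- .asMatrix(sc)
  isMat <- is.matrix(scM)
  if (isMat) {
    args <- c(list(sc = scM), lapply(predictors, .asMatrix))
    ed <- do.call(.sharedEdges, args)
    outcome <- ed$sc
    x <- as.matrix(ed[names(predictors)])
  } else {
    df <- data.frame(sc = scM, predictors)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    outcome <- df$sc
    x <- as.matrix(df[names(predictors)])
  }
  fit <- .logisticFit(outcome, x, pseudoR2)

  p <- NA_real_
  nulls <- numeric(0)
  if (nPerm > 0L) {
    if (!isMat || is.null(sphereCoords))
      stop("the spin null requires matrix input and sphereCoords")
    perms <- spinPermutation(sphereCoords, nPerm = nPerm, seed = seed)
    x1 <- .asMatrix(predictors[[1L]])
    nulls <- vapply(seq_len(nPerm), function(k) {
      pk <- perms[k, ]
      predsK <- predictors
      predsK[[1L]] <- x1[pk, pk, drop = FALSE]
      argsK <- c(list(sc = scM), lapply(predsK, .asMatrix))
      edk <- do.call(.sharedEdges, argsK)
      tryCatch(
        .logisticFit(edk$sc, as.matrix(edk[names(predictors)]), pseudoR2)$gof,
        error = function(e) NA_real_)
    }, numeric(1))
    p <- .permPValue(fit$gof, nulls, "greater")
  }
  new("FitResult", model = "logistic", coefficients = fit$coef,
      gof = fit$gof, gofType = pseudoR2, pValue = p,
      nEdges = length(outcome), extra = list(fitted = fit$fitted,
                                             nulls = nulls))
}

.logisticFit <- function(outcome, x, pseudoR2) {
  u <- unique(outcome[!is.na(outcome)])
  if (!all(u %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(u) < 2L) stop("single-class outcome: no variation to model")
  xs <- apply(x, 2L, .standardize)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, xs), outcome,
                   family = stats::binomial()))
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10))
    stop("complete (or quasi-complete) separation detected; ",
         "consider penalized/regularized estimation")
  llModel <- sum(outcome * log(mu) + (1 - outcome) * log(1 - mu))
  pbar <- mean(outcome)
  llNull <- sum(outcome * log(pbar) + (1 - outcome) * log(1 - pbar))
  n <- length(outcome)
  gof <- if (pseudoR2 == "mcfadden") 1 - llModel / llNull
         else 1 - exp((llNull - llModel) * 2 / n)
  list(coef = stats::coef(fit) %||% fit$coefficients, gof = gof, fitted = mu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed connection-probability curve
#'
#' Sorts the defined edges by a continuous predictor, splits them into
#' `nWindows` contiguous windows of near-equal size (sizes differ by at most
#' 1), and returns the mean predictor value, connection probability
#' (connected / total) and edge count per window.
#'
#' @param sc binary outcome (matrix or edge vector).
#' @param predictor continuous predictor, same shape.
#' @param nWindows number of windows (default 200).
#' @return data.frame with columns `window`, `meanPredictor`, `probability`,
#'   `nEdges`.
#' @export
windowProbabilityCurve <- function(sc, predictor, nWindows = 200L) {
  scM <- .asMatrix(sc)
  if (is.matrix(scM)) {
    ed <- .sharedEdges(sc = scM, x = .asMatrix(predictor))
    outcome <- ed$sc; x <- ed$x
  } else {
    keep <- stats::complete.cases(cbind(scM, predictor))
    outcome <- scM[keep]; x <- predictor[keep]
  }
  n <- length(outcome)
  if (n < nWindows) stop("need at least as many edges as windows")
  ord <- order(x)
  bounds <- floor(n * (0:nWindows) / nWindows)
  win <- rep(seq_len(nWindows), times = diff(bounds))
  data.frame(
    window = seq_len(nWindows),
    meanPredictor = as.vector(tapply(x[ord], win, mean)),
    probability = as.vector(tapply(outcome[ord], win, mean)),
    nEdges = as.vector(tapply(outcome[ord], win, length)))
}

#' Correlation of two edge sets
#'
#' Pearson or Spearman correlation over the mutually defined lower-triangle
#' edges (for matrices) or points (for vectors). For significance against
#' spatially constrained nulls use [correlationTest()].
#'
#' @param x,y matrices ([CovarianceMatrix-class] accepted) or vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return A [FitResult-class] with the correlation as `gof`.
#' @export
edgeCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xm <- .asMatrix(x); ym <- .asMatrix(y)
  if (is.matrix(xm)) {
    ed <- .sharedEdges(x = xm, y = ym)
    xv <- ed$x; yv <- ed$y
  } else {
    keep <- stats::complete.cases(cbind(xm, ym))
    xv <- xm[keep]; yv <- ym[keep]
  }
  if (length(xv) < 3L) stop("need at least 3 defined edges")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("undefined result: constant input")
  r <- stats::cor(xv, yv, method = method)
  new("FitResult", model = "correlation",
      coefficients = c(r = r), gof = r, gofType = "estimate",
      pValue = NA_real_, nEdges = length(xv), extra = list(method = method))
}

#' Restrict an edge table to long-range edges
#'
#' Keeps edges whose geodesic distance exceeds an absolute threshold in mm
#' or a distance quantile (default: the upper tercile). The cutoff defining
#' "long-range" is a free parameter.
#'
#' @param edges data.frame with a `gd` column (e.g. from [buildEdgeTable()]).
#' @param thresholdMm absolute cutoff in mm (overrides `quantile`).
#' @param quantile distance quantile cutoff in `[0, 1)` (default 2/3).
#' @return The filtered data.frame.
#' @export
subsetLongRange <- function(edges, thresholdMm = NULL, quantile = 2 / 3) {
  if (!"gd" %in% names(edges)) stop("edge table must have a 'gd' column")
  cut <- if (!is.null(thresholdMm)) thresholdMm
         else stats::quantile(edges$gd, quantile, na.rm = TRUE)
  out <- edges[!is.na(edges$gd) & edges$gd > cut, , drop = FALSE]
  if (!nrow(out)) stop("no edges remain above the long-range threshold")
  out
}

#' Build a lower-triangle edge table from parcel matrices
#'
#' One row per unordered parcel pair (i > j) with one column per supplied
#' matrix; rows where any matrix is undefined are dropped, matching the
#' convention that undefined edges are excluded from every fit.
#'
#' @param ... named P x P matrices ([CovarianceMatrix-class] accepted),
#'   e.g. `ltc = `, `gd = `, `sc = `, `fc = `.
#' @return data.frame with columns `i`, `j` and the named values.
#' @export
buildEdgeTable <- function(...) {
  mats <- lapply(list(...), .asMatrix)
  if (is.null(names(mats)) || any(names(mats) == ""))
    stop("all matrices must be named")
  do.call(.sharedEdges, mats)
}
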