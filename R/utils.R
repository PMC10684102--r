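## Internal helpers shared across modules.

## Deterministic seed splitting: one master seed fans out to per-module
## streams via repeated Lehmer (minimal-standard LCG) steps, so each generator
## can be re-run in isolation with a reproducible sub-seed. 48271 * 2^31 < 2^53,
## so the arithmetic is exact in doubles.
.splitSeed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  x <- (abs(as.numeric(seed)) + 12345) %% 2147483647
  if (x == 0) x <- 1
  for (i in seq_len(key + 2L)) x <- (48271 * x) %% 2147483647
  as.integer(x %% 2147483647)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Lower-triangle (i > j) index pairs of a P x P matrix.
.lowerPairs <- function(p) {
  j <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  i <- sequence((p - 1L):1L, from = 2L:p)
  cbind(i = i, j = j)
}

## Permutation p-value with the add-one convention; never 0.
.permPValue <- function(observed, nulls, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  nulls <- nulls[is.finite(nulls)]
  extreme <- switch(tail,
    two.sided = sum(abs(nulls) >= abs(observed)),
    greater   = sum(nulls >= observed),
    less      = sum(nulls <= observed))
  (1 + extreme) / (length(nulls) + 1)
}

.newNullDistribution <- function(observed, nulls, tail, seed) {
  new("NullDistribution", observed = as.numeric(observed),
      nulls = as.numeric(nulls),
      pValue = .permPValue(observed, nulls, tail),
      tail = tail, nPerm = length(nulls), seed = as.integer(seed))
}

## Column-wise standardization that errors on constant columns.
.standardize <- function(x, what = "predictor") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant ", what)
  (x - mean(x)) / s
}

.isSquare <- function(m) is.matrix(m) && nrow(m) == ncol(m)

## Extract defined lower-triangle edge values shared by several matrices.
## Returns a data.frame with i, j and one column per named matrix.
.sharedEdges <- function(...) {
  mats <- list(...)
  p <- nrow(mats[[1]])
  for (m in mats) {
    if (!.isSquare(m) || nrow(m) != p)
      stop("all matrices must be square with matching dimensions")
  }
  idx <- .lowerPairs(p)
  out <- data.frame(i = idx[, "i"], j = idx[, "j"])
  for (nm in names(mats)) out[[nm]] <- mats[[nm]][idx]
  keep <- stats::complete.cases(out)
  out[keep, , drop = FALSE]
}

## Place edge values back into a symmetric matrix with NA elsewhere.
.edgesToMatrix <- function(i, j, x, p, dimNames = NULL) {
  m <- matrix(NA_real_, p, p, dimnames = dimNames)
  m[cbind(i, j)] <- x
  m[cbind(j, i)] <- x
  m
}

.asMatrix <- function(x) if (is(x, "CovarianceMatrix")) x@values else x
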