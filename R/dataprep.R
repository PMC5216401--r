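#' Clean a descriptor table
#'
#' Drops every descriptor that is missing for at least one ligand or shows
#' little or no discrimination: sample sd below `minSd`, or at most one
#' distinct value. Rows (ligands) are never touched.
#'
#' @param table a [DescriptorTable-class].
#' @param minSd minimum sample standard deviation to keep a column.
#' @return the cleaned [DescriptorTable-class].
#' @export
cleanDescriptors <- function(table, minSd = 1e-8) {
  stopifnot(is(table, "DescriptorTable"))
  v <- descriptorMatrix(table)
  if (nrow(v) < 2) .stopf("need at least 2 ligands to assess discrimination")
  keep <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    !anyNA(x) && length(unique(x)) > 1L && stats::sd(x) >= minSd
  }, logical(1))
  if (!any(keep)) .stopf("cleaning removed every descriptor column")
  table[, keep]
}

#' Remove intercorrelated descriptors
#'
#' Iteratively drops descriptors until no surviving pair has squared Pearson
#' correlation >= `r2Threshold` (default 0.64, i.e. |r| >= 0.8). Within an
#' offending pair the column less correlated (|r|) with `target` is dropped
#' when a target is supplied; otherwise the later column is dropped.
#'
#' @param table a cleaned [DescriptorTable-class].
#' @param r2Threshold squared-correlation cutoff.
#' @param target optional response vector (one value per ligand) guiding
#'   which member of a correlated pair is kept.
#' @return the filtered [DescriptorTable-class].
#' @export
filterIntercorrelated <- function(table, r2Threshold = 0.64, target = NULL) {
  stopifnot(is(table, "DescriptorTable"))
  v <- descriptorMatrix(table)
  if (anyNA(v)) .stopf("missing values present; run cleanDescriptors first")
  if (!is.null(target) && length(target) != nrow(v))
    .stopf("target length must equal the number of ligands")
  keep <- seq_len(ncol(v))
  if (ncol(v) >= 2) {
    r2 <- suppressWarnings(stats::cor(v))^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 1  # zero-variance columns count as redundant
    tcor <- if (is.null(target)) rep(0, ncol(v))
            else abs(suppressWarnings(stats::cor(v, target)))[, 1L]
    tcor[is.na(tcor)] <- 0
    repeat {
      sub <- r2[keep, keep, drop = FALSE]
      worst <- which(sub >= r2Threshold, arr.ind = TRUE)
      worst <- worst[worst[, 1] != worst[, 2], , drop = FALSE]
      if (!nrow(worst)) break
      i <- keep[worst[1L, 1L]]; j <- keep[worst[1L, 2L]]
      # drop the less target-relevant column; earlier column wins ties
      drop <- if (tcor[i] > tcor[j]) j
              else if (tcor[j] > tcor[i]) i
              else max(i, j)
      keep <- setdiff(keep, drop)
    }
  }
  table[, keep]
}

#' Fit / apply a z-score normalizer
#'
#' Normalization statistics (per-feature mean and sample sd) are computed on
#' the training rows only; applying the fitted statistics to those rows gives
#' column means 0 and sds 1, and held-out rows reuse the training statistics.
#'
#' @param table a [DescriptorTable-class] or numeric matrix.
#' @param trainIds ligand ids (or row indices) defining the training rows;
#'   default all rows.
#' @return `fitNormalizer`: list of class `"NormalizerStats"` with `center`,
#'   `scale` and `featureNames`.
#' @export
fitNormalizer <- function(table, trainIds = NULL) {
  v <- if (is(table, "DescriptorTable")) descriptorMatrix(table) else as.matrix(table)
  rows <- if (is.null(trainIds)) seq_len(nrow(v)) else trainIds
  tr <- v[rows, , drop = FALSE]
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, stats::sd)
  if (any(!is.finite(scl)) || any(scl <= 0))
    .stopf("zero-variance feature(s) on the training rows: %s; run cleanDescriptors first",
           paste(colnames(v)[!is.finite(scl) | scl <= 0], collapse = ", "))
  out <- list(center = ctr, scale = scl, featureNames = colnames(v))
  class(out) <- c("NormalizerStats", "list")
  out
}

#' @rdname fitNormalizer
#' @param stats a `"NormalizerStats"` object.
#' @return `applyNormalizer`: object of the same shape with normalized values.
#' @export
applyNormalizer <- function(stats, table) {
  isDT <- is(table, "DescriptorTable")
  v <- if (isDT) descriptorMatrix(table) else as.matrix(table)
  v <- v[, stats$featureNames, drop = FALSE]
  z <- sweep(sweep(v, 2, stats$center, "-"), 2, stats$scale, "/")
  if (isDT) DescriptorTable(z) else z
}

#' @rdname fitNormalizer
#' @return `invertNormalizer`: the original-scale values.
#' @export
invertNormalizer <- function(stats, table) {
  isDT <- is(table, "DescriptorTable")
  z <- if (isDT) descriptorMatrix(table) else as.matrix(table)
  v <- sweep(sweep(z[, stats$featureNames, drop = FALSE], 2, stats$scale, "*"),
             2, stats$center, "+")
  if (isDT) DescriptorTable(v) else v
}

#' Kennard-Stone train/test split
#'
#' Classical maximin coverage design: the pair realizing the maximum
#' Euclidean distance enters the training set first; points are then added
#' one at a time by maximizing the minimum distance to the already-selected
#' set, until the training set holds `floor(n * r / (r + 1))` points for a
#' ratio `r`:1 (24/13 for 37 points at 2:1). All ties break toward the lowest
#' row index, so the split is deterministic given the input order.
#'
#' @param X numeric matrix (rows = samples); rownames, if present, are used
#'   as ids.
#' @param ratio train:test ratio `r` (default 2 for 2:1).
#' @param trainSize override the computed training-set size.
#' @return list of class `"SplitResult"`: `trainIds` (in selection order),
#'   `testIds`, `ratio`.
#' @export
kennardStoneSplit <- function(X, ratio = 2, trainSize = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) .stopf("need at least 2 rows to split")
  if (anyNA(X)) .stopf("missing values in the split design matrix")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nTrain <- if (is.null(trainSize)) floor(n * ratio / (ratio + 1)) else trainSize
  nTrain <- max(1L, min(n - 1L, as.integer(nTrain)))
  D <- as.matrix(stats::dist(X))
  # seed pair: global maximum distance, lowest indices on ties
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1L, ])
  if (nTrain == 1L) sel <- sel[1L]
  while (length(sel) < nTrain) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(dmin)])  # which.max takes the lowest index on ties
  }
  out <- list(trainIds = ids[sel], testIds = ids[setdiff(seq_len(n), sel)],
              ratio = ratio)
  class(out) <- c("SplitResult", "list")
  out
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult: %d train / %d test (ratio %g:1)\n",
              length(x$trainIds), length(x$testIds), x$ratio))
  invisible(x)
}

#' Descriptive diagnostics of a train/test split
#'
#' Summarizes how the two sets cover response and descriptor space:
#' per-set pKi summaries and histogram counts on shared breaks, per-set
#' descriptor means, and the fraction of descriptor variance explained by
#' the leading principal components of the pooled data.
#'
#' @param descriptors a [DescriptorTable-class] (cleaned).
#' @param affinities an [AffinityTable-class].
#' @param split a `"SplitResult"`.
#' @param nPc number of leading principal components to report.
#' @return list with `pkiSummary`, `pkiHist`, `descriptorMeans`,
#'   `pcVariance`.
#' @export
splitDiagnostics <- function(descriptors, affinities, split, nPc = 3) {
  stopifnot(is(descriptors, "DescriptorTable"), is(affinities, "AffinityTable"))
  v <- descriptorMatrix(descriptors)
  pki <- pKi(affinities)
  ids <- list(train = split$trainIds, test = split$testIds)
  if (!all(unlist(ids) %in% rownames(v)) || !all(unlist(ids) %in% names(pki)))
    .stopf("split ids absent from descriptor or affinity table")
  breaks <- pretty(range(pki[unlist(ids)]), 10)
  pkiHist <- lapply(ids, function(i)
    graphics::hist(pki[i], breaks = breaks, plot = FALSE)$counts)
  pc <- stats::prcomp(v[unlist(ids), , drop = FALSE], center = TRUE,
                      scale. = FALSE)
  varExp <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    pkiSummary = lapply(ids, function(i) summary(pki[i])),
    pkiHist = c(list(breaks = breaks), pkiHist),
    descriptorMeans = lapply(ids, function(i) colMeans(v[i, , drop = FALSE])),
    pcVariance = utils::head(varExp, nPc))
}
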