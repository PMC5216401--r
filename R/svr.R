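# RBF-kernel SVR core. Fitting is delegated to e1071 (libsvm); the fitted
# dual solution is copied into an SvrArtifact and every prediction in this
# package is computed from the artifact's own arrays, keeping predictions
# exactly reproducible across save/load.

.fitSvrRaw <- function(X, y, mode, C, gamma, epsilon = NA_real_, nu = NA_real_) {
  if (mode == "eps") {
    fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = C, gamma = gamma, epsilon = epsilon, scale = FALSE)
  } else {
    fit <- e1071::svm(X, y, type = "nu-regression", kernel = "radial",
                      cost = C, gamma = gamma, nu = nu, scale = FALSE)
  }
  list(SV = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
       rho = as.numeric(fit$rho))
}

# decision function sum_i coefs_i K(sv_i, x) - rho, K = RBF
.predictSvrRaw <- function(raw, gamma, X) {
  X <- as.matrix(X)
  sv <- raw$SV
  d2 <- outer(rowSums(X^2), rep(1, nrow(sv))) +
        outer(rep(1, nrow(X)), rowSums(sv^2)) - 2 * tcrossprod(X, sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-gamma * d2) %*% raw$coefs - raw$rho)
}

.newSvrArtifact <- function(kind, structureId, hp, featureNames, center, scale,
                            raw, meta = list()) {
  new("SvrArtifact", kind = kind,
      structureId = if (is.null(structureId)) NA_character_ else structureId,
      mode = hp$mode, cost = hp$C, gamma = hp$gamma,
      epsilon = if (hp$mode == "eps") hp$epsilon else NA_real_,
      nu = if (hp$mode == "nu") hp$nu else NA_real_,
      featureNames = featureNames, center = center, scale = scale,
      SV = raw$SV, coefs = raw$coefs, rho = raw$rho,
      version = .ARTIFACT_VERSION, meta = meta)
}

#' Predict from a fitted SVR artifact
#'
#' Applies the artifact's stored normalization, evaluates the RBF decision
#' function from the stored support vectors, and (for pose-kind artifacts)
#' clips negative RMSD predictions to zero, flagging clipped rows in the
#' `"clipped"` attribute.
#'
#' @param artifact an [SvrArtifact-class].
#' @param X numeric matrix (or data.frame) whose columns are matched to the
#'   artifact's feature list by name when column names are present.
#' @param clip clip predictions at zero (default: pose-kind only).
#' @return numeric predictions, one per row of `X`.
#' @export
predictSvr <- function(artifact, X, clip = artifact@kind == "pose") {
  stopifnot(is(artifact, "SvrArtifact"))
  X <- as.matrix(X)
  fn <- artifact@featureNames
  if (!is.null(colnames(X))) {
    extra <- setdiff(colnames(X), fn)
    miss <- setdiff(fn, colnames(X))
    if (length(miss))
      .stopf("feature column(s) missing: %s", paste(miss, collapse = ", "))
    if (length(extra))
      .stopf("unknown feature column(s): %s", paste(extra, collapse = ", "))
    X <- X[, fn, drop = FALSE]
  } else if (ncol(X) != length(fn)) {
    .stopf("expected %d feature columns, got %d", length(fn), ncol(X))
  }
  Z <- sweep(sweep(X, 2, artifact@center, "-"), 2, artifact@scale, "/")
  p <- .predictSvrRaw(list(SV = artifact@SV, coefs = artifact@coefs,
                           rho = artifact@rho), artifact@gamma, Z)
  if (!all(is.finite(p))) .stopf("non-finite SVR prediction")
  if (clip) {
    clipped <- p < 0
    p[clipped] <- 0
    attr(p, "clipped") <- clipped
  }
  p
}

#' Hyperparameter grid for SVR scanning
#'
#' Builds the lattice of (mode, C, gamma, epsilon/nu) combinations scanned by
#' [gridScanSvr()]. The full default covers C in 2^(-5..15), gamma in
#' 2^(-15..3) (steps of 2^2), epsilon in {0.01,0.05,0.1,0.2,0.5} and nu in
#' {0.2,0.4,0.5,0.6,0.8} for both regression modes; `coarse = TRUE` is a
#' condensed lattice for the bundled benchmarks.
#'
#' @param C,gamma,epsilon,nu candidate values.
#' @param modes regression modes to scan ("eps", "nu").
#' @param coarse use the condensed default lattice.
#' @return data.frame with columns mode, C, gamma, epsilon, nu (one of
#'   epsilon/nu is NA per row).
#' @export
defaultSvrGrid <- function(C = NULL, gamma = NULL, epsilon = NULL, nu = NULL,
                           modes = c("eps", "nu"), coarse = FALSE) {
  if (is.null(C)) C <- if (coarse) 2^c(-1, 3, 7, 11) else 2^seq(-5, 15, 2)
  if (is.null(gamma)) gamma <- if (coarse) 2^c(-6, -3, 0) else 2^seq(-15, 3, 2)
  if (is.null(epsilon)) epsilon <- if (coarse) c(0.01, 0.1, 0.5) else c(0.01, 0.05, 0.1, 0.2, 0.5)
  if (is.null(nu)) nu <- if (coarse) 0.5 else c(0.2, 0.4, 0.5, 0.6, 0.8)
  g <- NULL
  if ("eps" %in% modes)
    g <- rbind(g, expand.grid(mode = "eps", C = C, gamma = gamma,
                              epsilon = epsilon, nu = NA_real_,
                              stringsAsFactors = FALSE))
  if ("nu" %in% modes)
    g <- rbind(g, expand.grid(mode = "nu", C = C, gamma = gamma,
                              epsilon = NA_real_, nu = nu,
                              stringsAsFactors = FALSE))
  if (is.null(g) || !nrow(g)) .stopf("empty hyperparameter grid")
  rownames(g) <- NULL
  g
}

#' Cross-validated grid scan over SVR hyperparameters
#'
#' Every grid point is evaluated by k-fold cross-validated q2
#' (1 - PRESS/SS_tot, out-of-fold predictions, shared seeded folds), and the
#' point maximizing q2cv wins. Ties are broken toward the flatter model:
#' smaller C, then larger epsilon, then grid order. Grid points are
#' independent of each other, so the scan order does not affect the result.
#'
#' @param X normalized numeric feature matrix.
#' @param y numeric response.
#' @param grid data.frame as produced by [defaultSvrGrid()].
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `best` (one-row data.frame), `q2cv` (at the optimum) and
#'   `scan` (the full grid with a q2cv column).
#' @export
gridScanSvr <- function(X, y, grid = defaultSvrGrid(coarse = TRUE),
                        folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (!nrow(grid)) .stopf("empty hyperparameter grid")
  if (nrow(X) < folds)
    .stopf("n = %d is smaller than folds = %d", nrow(X), folds)
  fold <- .makeFolds(y, folds, seed)
  ssTot <- sum((y - mean(y))^2)
  q2 <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- as.list(grid[i, ])
    pred <- rep(NA_real_, length(y))
    for (f in unique(fold)) {
      tr <- fold != f
      raw <- .fitSvrRaw(X[tr, , drop = FALSE], y[tr], hp$mode, hp$C,
                        hp$gamma, hp$epsilon, hp$nu)
      pred[!tr] <- .predictSvrRaw(raw, hp$gamma, X[!tr, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / ssTot
  }, numeric(1))
  scan <- cbind(grid, q2cv = q2)
  ord <- order(-round(q2, 12), grid$C, -ifelse(is.na(grid$epsilon), -Inf,
                                               grid$epsilon),
               seq_len(nrow(grid)))
  best <- ord[1L]
  list(best = grid[best, , drop = FALSE], q2cv = q2[best], scan = scan)
}

# fit at fixed hyperparameters, embedding the normalizer computed from X
.trainSvrArtifact <- function(X, y, kind, structureId, grid, folds, seed,
                              meta = list()) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl <= 0))
    .stopf("zero-variance feature(s): %s; clean before training",
           paste(colnames(X)[scl <= 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  scan <- gridScanSvr(Z, y, grid, folds = folds, seed = seed)
  hp <- as.list(scan$best)
  raw <- .fitSvrRaw(Z, y, hp$mode, hp$C, hp$gamma, hp$epsilon, hp$nu)
  fitPred <- .predictSvrRaw(raw, hp$gamma, Z)
  meta <- c(meta, list(n = nrow(X), q2cv = scan$q2cv,
                       trainR2 = .pearsonR2(y, fitPred)))
  .newSvrArtifact(kind, structureId, hp, colnames(X), ctr, scl, raw, meta)
}
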