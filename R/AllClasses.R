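#' PoseTable: docked-pose candidates with scoring-term features
#'
#' One row per candidate pose, keyed by
#' (`ligand_id`, `structure_id`, `conformer_id`, `run_id`, `pose_id`).
#' All remaining numeric columns are scoring-function interaction terms
#' ("features"); `observed_rmsd` (Angstrom, >= 0) is optional and may contain
#' `NA` for unlabeled candidates.
#'
#' @slot data data.frame holding the five key columns, the feature columns and
#'   optionally `observed_rmsd`.
#' @slot featureNames character vector naming the feature columns, in order.
#' @export
setClass("PoseTable",
  representation(data = "data.frame", featureNames = "character"))

setValidity("PoseTable", function(object) {
  df <- object@data
  msgs <- character()
  miss <- setdiff(.keyCols, names(df))
  if (length(miss))
    msgs <- c(msgs, paste("missing key column(s):", paste(miss, collapse = ", ")))
  else {
    ks <- .keyString(df)
    if (anyDuplicated(ks))
      msgs <- c(msgs, sprintf("duplicate candidate key(s), e.g. row %d",
                              which(duplicated(ks))[1L]))
    for (k in c("conformer_id", "run_id", "pose_id"))
      if (any(!is.finite(df[[k]]) | df[[k]] < 1))
        msgs <- c(msgs, sprintf("'%s' must be positive integers", k))
  }
  miss <- setdiff(object@featureNames, names(df))
  if (length(miss))
    msgs <- c(msgs, paste("feature column(s) absent from data:",
                          paste(miss, collapse = ", ")))
  for (f in intersect(object@featureNames, names(df)))
    if (!is.numeric(df[[f]]))
      msgs <- c(msgs, sprintf("feature column '%s' is not numeric", f))
  if ("observed_rmsd" %in% names(df)) {
    r <- df$observed_rmsd
    if (!is.numeric(r) || any(r < 0, na.rm = TRUE))
      msgs <- c(msgs, "'observed_rmsd' must be numeric and >= 0 where present")
  }
  if (length(msgs)) msgs else TRUE
})

#' DescriptorTable: per-ligand molecular descriptors
#'
#' A rectangular block of named real-valued molecular descriptors, one row per
#' ligand. Missing values are permitted before cleaning
#' (see [cleanDescriptors()]).
#'
#' @slot values numeric matrix, rownames = ligand ids, colnames = descriptor
#'   names.
#' @export
setClass("DescriptorTable", representation(values = "matrix"))

setValidity("DescriptorTable", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "descriptor values must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "ligand ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "descriptor names (colnames) must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' AffinityTable: per-ligand binding affinities
#'
#' Affinities are stored as pKi = -log10(Ki in molar); higher means tighter
#' binding. `boundFlag` marks co-crystallized ligands, `setLabel` records the
#' train/test assignment ("train", "test" or "unassigned").
#'
#' @slot ligandIds character vector of unique ligand ids.
#' @slot pKi numeric vector of finite pKi values.
#' @slot boundFlag logical vector.
#' @slot setLabel character vector.
#' @export
setClass("AffinityTable",
  representation(ligandIds = "character", pKi = "numeric",
                 boundFlag = "logical", setLabel = "character"))

setValidity("AffinityTable", function(object) {
  msgs <- character()
  n <- length(object@ligandIds)
  if (anyDuplicated(object@ligandIds)) msgs <- c(msgs, "ligand ids must be unique")
  if (length(object@pKi) != n || any(!is.finite(object@pKi)))
    msgs <- c(msgs, "pKi must be finite and match ligand ids in length")
  if (length(object@boundFlag) != n || length(object@setLabel) != n)
    msgs <- c(msgs, "boundFlag/setLabel length mismatch")
  if (!all(object@setLabel %in% c("train", "test", "unassigned")))
    msgs <- c(msgs, "setLabel must be train/test/unassigned")
  if (length(msgs)) msgs else TRUE
})

#' SvrArtifact: a fitted support-vector regression model
#'
#' Self-contained RBF-kernel SVR artifact: hyperparameters, the per-feature
#' normalization statistics fitted on the training rows, and the fitted dual
#' parameters (support vectors, coefficients, offset). Prediction is computed
#' from these slots directly, so a saved and re-loaded artifact reproduces its
#' predictions bit-for-bit (see [saveModel()]).
#'
#' @slot kind "pose" (feature -> RMSD) or "score" (feature -> pKi).
#' @slot structureId protein-structure id for pose-kind models, `NA` otherwise.
#' @slot mode "eps" or "nu" regression.
#' @slot C,gamma,epsilon,nu SVR hyperparameters (the inactive one of
#'   epsilon/nu is `NA`).
#' @slot featureNames ordered feature list the model was trained on.
#' @slot center,scale per-feature normalization statistics (training mean, sd).
#' @slot SV support-vector matrix in normalized feature space.
#' @slot coefs dual coefficients (one per support vector).
#' @slot rho decision-function offset.
#' @slot version artifact format tag.
#' @slot meta list of training metadata (n, trainR2, q2cv, ...).
#' @export
setClass("SvrArtifact",
  representation(kind = "character", structureId = "character",
                 mode = "character", cost = "numeric", gamma = "numeric",
                 epsilon = "numeric", nu = "numeric",
                 featureNames = "character", center = "numeric",
                 scale = "numeric", SV = "matrix", coefs = "numeric",
                 rho = "numeric", version = "character", meta = "list"))

setValidity("SvrArtifact", function(object) {
  msgs <- character()
  if (!object@kind %in% c("pose", "score")) msgs <- c(msgs, "kind must be pose/score")
  if (!object@mode %in% c("eps", "nu")) msgs <- c(msgs, "mode must be eps/nu")
  if (object@cost <= 0 || object@gamma <= 0) msgs <- c(msgs, "C and gamma must be > 0")
  p <- length(object@featureNames)
  if (ncol(object@SV) != p || length(object@center) != p || length(object@scale) != p)
    msgs <- c(msgs, "feature dimension mismatch between SV/center/scale/featureNames")
  if (nrow(object@SV) != length(object@coefs))
    msgs <- c(msgs, "one dual coefficient per support vector required")
  if (any(object@scale <= 0)) msgs <- c(msgs, "normalization sd must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' PoseModelSet: one pose-RMSD model per protein structure
#'
#' @slot models named list of pose-kind [SvrArtifact-class] objects, one per
#'   structure id.
#' @slot featureNames shared ordered feature list.
#' @slot meta data.frame of per-structure training metadata
#'   (structure_id, n, q2cv, trainR2).
#' @export
setClass("PoseModelSet",
  representation(models = "list", featureNames = "character",
                 meta = "data.frame"))

setValidity("PoseModelSet", function(object) {
  msgs <- character()
  if (is.null(names(object@models)) || anyDuplicated(names(object@models)))
    msgs <- c(msgs, "models must be uniquely named by structure id")
  for (m in object@models) {
    if (!is(m, "SvrArtifact") || m@kind != "pose")
      msgs <- c(msgs, "all members must be pose-kind SvrArtifact objects")
    else if (!identical(m@featureNames, object@featureNames))
      msgs <- c(msgs, "all members must share the set's feature list")
  }
  if (length(msgs)) unique(msgs) else TRUE
})
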