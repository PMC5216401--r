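#' Assemble the affinity-model feature matrix
#'
#' One row per ligand, built only from that ligand's single selected pose:
#' the configured scoring-term columns are taken from the selected pose's row
#' of the pose table, and the configured molecular descriptors from the
#' descriptor table. Column order follows the config, independent of input
#' row order.
#'
#' @param selectedPoses data.frame of selected candidate keys
#'   ([selectTopPose()]).
#' @param poseTable the [PoseTable-class] the selections refer to.
#' @param descriptorTable a [DescriptorTable-class].
#' @param poseTerms scoring-term columns to include (default: none).
#' @param descriptorNames descriptor columns to include (default: all).
#' @return numeric matrix, rownames = ligand ids, columns = poseTerms then
#'   descriptors.
#' @export
buildScoreFeatures <- function(selectedPoses, poseTable, descriptorTable,
                               poseTerms = character(0),
                               descriptorNames = NULL) {
  stopifnot(is(poseTable, "PoseTable"), is(descriptorTable, "DescriptorTable"))
  df <- as.data.frame(poseTable)
  dm <- descriptorMatrix(descriptorTable)
  if (is.null(descriptorNames)) descriptorNames <- colnames(dm)
  missD <- setdiff(descriptorNames, colnames(dm))
  if (length(missD))
    .stopf("unknown descriptor(s): %s", paste(missD, collapse = ", "))
  missT <- setdiff(poseTerms, featureNames(poseTable))
  if (length(missT))
    .stopf("unknown scoring term(s): %s", paste(missT, collapse = ", "))
  sel <- selectedPoses[order(selectedPoses$ligand_id), , drop = FALSE]
  lig <- sel$ligand_id
  if (anyDuplicated(lig)) .stopf("multiple selected poses for a ligand")
  noDesc <- setdiff(lig, rownames(dm))
  if (length(noDesc))
    .stopf("ligand(s) missing from descriptor table: %s",
           paste(noDesc, collapse = ", "))
  rowIdx <- match(.keyString(sel), .keyString(df))
  if (anyNA(rowIdx))
    .stopf("selected pose(s) absent from pose table: %s",
           paste(lig[is.na(rowIdx)], collapse = ", "))
  out <- cbind(
    as.matrix(df[rowIdx, poseTerms, drop = FALSE]),
    dm[lig, descriptorNames, drop = FALSE])
  rownames(out) <- lig
  colnames(out) <- c(poseTerms, descriptorNames)
  if (anyNA(out)) .stopf("missing cells in the score feature matrix")
  out
}

#' Train the affinity (pKi) model
#'
#' RBF-kernel SVR from selected-pose features to pKi, trained on the rows of
#' `features` named in `split$trainIds`, with hyperparameters from
#' [gridScanSvr()]. The response is always pKi, keeping the regression scale
#' log-linear.
#'
#' @param features matrix from [buildScoreFeatures()] (rownames = ligand
#'   ids).
#' @param affinities an [AffinityTable-class].
#' @param split a `"SplitResult"` ([kennardStoneSplit()]); test rows are
#'   never touched during fitting.
#' @param grid hyperparameter lattice.
#' @param folds,seed CV-scan controls.
#' @return a score-kind [SvrArtifact-class]; `meta` carries n, q2cv and
#'   training r2.
#' @export
trainScoreModel <- function(features, affinities, split,
                            grid = defaultSvrGrid(coarse = TRUE),
                            folds = 10, seed = 1) {
  stopifnot(is(affinities, "AffinityTable"))
  y <- pKi(affinities)
  trainIds <- split$trainIds
  miss <- setdiff(trainIds, rownames(features))
  if (length(miss))
    .stopf("training ligand(s) missing from features: %s",
           paste(miss, collapse = ", "))
  miss <- setdiff(trainIds, names(y))
  if (length(miss))
    .stopf("training ligand(s) missing from affinities: %s",
           paste(miss, collapse = ", "))
  ytr <- y[trainIds]
  if (length(ytr) < 10) .stopf("need >= 10 training ligands, got %d", length(ytr))
  if (stats::sd(ytr) == 0) .stopf("degenerate response: zero pKi variance")
  X <- features[trainIds, , drop = FALSE]
  .trainSvrArtifact(X, as.numeric(ytr), "score", NULL, grid, folds,
                    stageSeed(seed, "score"))
}

#' Predict pKi from an affinity model
#'
#' Columns are matched to the model's feature list by name; a missing or
#' unknown column is an error naming the discrepancy.
#'
#' @param model a score-kind [SvrArtifact-class].
#' @param features numeric matrix with named columns.
#' @return named numeric vector of predicted pKi (one per row).
#' @export
predictPki <- function(model, features) {
  stopifnot(is(model, "SvrArtifact"))
  if (model@kind != "score") .stopf("expected a score-kind model")
  p <- predictSvr(model, features, clip = FALSE)
  stats::setNames(p, rownames(features))
}

#' End-to-end rescoring pipeline
#'
#' Chains the trained stages over a candidate ensemble: per-structure pose
#' RMSD prediction, top-pose selection per ligand, score-feature assembly,
#' and pKi prediction. The result is one report row per ligand; the
#' intermediate per-candidate predictions and selections are attached for
#' audit.
#'
#' @param poseTable candidate ensemble ([PoseTable-class]).
#' @param descriptorTable a [DescriptorTable-class].
#' @param poseModelSet a trained [PoseModelSet-class].
#' @param scoreModel a trained score-kind [SvrArtifact-class].
#' @param poseTerms scoring-term columns fed to the score model (must match
#'   how `scoreModel` was trained).
#' @param descriptorNames descriptor columns fed to the score model.
#' @return data.frame (ligand_id, selected pose key, predicted_rmsd,
#'   predicted_pki) with attributes `"predictions"` and `"selections"`.
#' @export
runPipeline <- function(poseTable, descriptorTable, poseModelSet, scoreModel,
                        poseTerms = character(0), descriptorNames = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (length(poseTable) == 0L) {
    out <- data.frame(ligand_id = character(0), structure_id = character(0),
                      conformer_id = integer(0), run_id = integer(0),
                      pose_id = integer(0), predicted_rmsd = numeric(0),
                      predicted_pki = numeric(0))
    return(out)
  }
  pred <- stage("pose-rmsd-prediction",
                predictPoseRmsd(poseModelSet, poseTable))
  sel <- stage("top-pose-selection", selectTopPose(pred))
  feats <- stage("score-feature-assembly",
                 buildScoreFeatures(sel, poseTable, descriptorTable,
                                    poseTerms, descriptorNames))
  pki <- stage("pki-prediction", predictPki(scoreModel, feats))
  out <- sel[order(sel$ligand_id), , drop = FALSE]
  out$predicted_pki <- as.numeric(pki[out$ligand_id])
  rownames(out) <- NULL
  attr(out, "predictions") <- pred
  attr(out, "selections") <- sel
  out
}
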