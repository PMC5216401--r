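#' Train a per-structure pose-RMSD model
#'
#' Fits an RBF-kernel SVR mapping the scoring-term features of docked poses
#' of one protein structure to their observed RMSD (Angstrom). Hyperparameters
#' are chosen by [gridScanSvr()]; the feature normalizer (training mean/sd) is
#' embedded in the artifact. Rows of other structures are ignored; rows of the
#' requested structure lacking an observed RMSD are an error.
#'
#' @param structureId which structure to train on.
#' @param poseTable a [PoseTable-class] with observed RMSD for that structure.
#' @param grid hyperparameter lattice ([defaultSvrGrid()]).
#' @param folds CV folds of the scan.
#' @param seed integer seed.
#' @param minPoses minimum labeled poses required (default 10; a typical
#'   redocking protocol provides 30 = 10 runs x 3 poses).
#' @return a pose-kind [SvrArtifact-class] with training r2 and q2cv in
#'   `meta`.
#' @export
trainPoseModel <- function(structureId, poseTable,
                           grid = defaultSvrGrid(coarse = TRUE),
                           folds = 10, seed = 1, minPoses = 10) {
  stopifnot(is(poseTable, "PoseTable"))
  df <- as.data.frame(poseTable)
  rows <- df$structure_id == structureId
  if (!any(rows)) .stopf("no poses for structure '%s'", structureId)
  r <- observedRmsd(poseTable)[rows]
  if (anyNA(r)) {
    bad <- .keyString(df[rows, ][is.na(r), ])
    .stopf("structure '%s': %d pose(s) lack observed RMSD (e.g. %s)",
           structureId, sum(is.na(r)), gsub("\r", "/", bad[1L]))
  }
  if (sum(rows) < minPoses)
    .stopf("structure '%s': only %d labeled pose(s), need >= %d",
           structureId, sum(rows), minPoses)
  X <- poseFeatures(poseTable)[rows, , drop = FALSE]
  .trainSvrArtifact(X, r, "pose", structureId, grid, folds,
                    stageSeed(seed, paste0("pose:", structureId)))
}

#' Train one pose-RMSD model per structure
#'
#' @param poseTable a [PoseTable-class]; every structure present must have
#'   enough labeled poses.
#' @inheritParams trainPoseModel
#' @return a [PoseModelSet-class].
#' @export
trainPoseModelSet <- function(poseTable, grid = defaultSvrGrid(coarse = TRUE),
                              folds = 10, seed = 1, minPoses = 10) {
  stopifnot(is(poseTable, "PoseTable"))
  structs <- sort(structureIds(poseTable))
  models <- lapply(structs, function(s)
    tryCatch(trainPoseModel(s, poseTable, grid, folds, seed, minPoses),
             error = function(e)
               .stopf("structure '%s' undertrained: %s", s,
                      conditionMessage(e))))
  names(models) <- structs
  meta <- do.call(rbind, lapply(models, function(m)
    data.frame(structure_id = m@structureId, n = m@meta$n,
               q2cv = m@meta$q2cv, trainR2 = m@meta$trainR2,
               stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  new("PoseModelSet", models = models,
      featureNames = models[[1L]]@featureNames, meta = meta)
}

#' Predict pose RMSD for every candidate
#'
#' Each row is scored by the model of its own structure; an unknown
#' structure id is an error (no silent fallback). Raw negative predictions
#' are clipped to 0 and flagged in the `clipped` column.
#'
#' @param modelSet a [PoseModelSet-class].
#' @param poseTable a [PoseTable-class].
#' @return data.frame: the five key columns, `predicted_rmsd`, `clipped`.
#' @export
predictPoseRmsd <- function(modelSet, poseTable) {
  stopifnot(is(modelSet, "PoseModelSet"), is(poseTable, "PoseTable"))
  df <- as.data.frame(poseTable)
  unknown <- setdiff(unique(df$structure_id), structureIds(modelSet))
  if (length(unknown))
    .stopf("no model for structure id(s): %s", paste(unknown, collapse = ", "))
  X <- poseFeatures(poseTable)
  pred <- rep(NA_real_, nrow(df))
  clip <- rep(FALSE, nrow(df))
  for (s in unique(df$structure_id)) {
    rows <- df$structure_id == s
    p <- predictSvr(modelSet[[s]], X[rows, , drop = FALSE])
    pred[rows] <- p
    clip[rows] <- attr(p, "clipped")
  }
  out <- df[, .keyCols]
  out$predicted_rmsd <- pred
  out$clipped <- clip
  out
}

#' Select the top pose per ligand
#'
#' Within each group (default: ligand, i.e. across all structures, conformers,
#' runs and poses of the candidate ensemble), the candidate with the lowest
#' predicted RMSD is selected; exact ties break lexicographically by
#' (structure_id, conformer_id, run_id, pose_id).
#'
#' @param predictions data.frame from [predictPoseRmsd()] (key columns +
#'   `predicted_rmsd`).
#' @param groupBy grouping column(s), default `"ligand_id"`.
#' @return data.frame with one selected candidate key per group plus its
#'   `predicted_rmsd`.
#' @export
selectTopPose <- function(predictions, groupBy = "ligand_id") {
  df <- predictions
  if (!all(c(.keyCols, "predicted_rmsd") %in% names(df)))
    .stopf("predictions must carry the key columns and 'predicted_rmsd'")
  grp <- interaction(df[groupBy], drop = TRUE)
  if (!nlevels(grp)) .stopf("no candidates to select from")
  tie <- paste(df$structure_id,
               sprintf("%09d", df$conformer_id),
               sprintf("%09d", df$run_id),
               sprintf("%09d", df$pose_id))
  picked <- vapply(levels(grp), function(g) {
    idx <- which(grp == g)
    idx[order(df$predicted_rmsd[idx], tie[idx])][1L]
  }, integer(1))
  out <- df[picked, c(.keyCols, "predicted_rmsd"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-structure transfer matrix
#'
#' Applies every structure's pose model to every structure's labeled poses
#' and reports the squared Pearson correlation between predicted and observed
#' RMSD. Row = model, column = evaluation structure; the diagonal is native
#' performance. Degradation off the diagonal indicates that pose-RMSD
#' relationships are structure-specific and no single model transfers.
#'
#' @param modelSet a [PoseModelSet-class].
#' @param poseTable a [PoseTable-class] with observed RMSD for all rows used.
#' @return S x S numeric matrix (dimnames = structure ids).
#' @export
crossStructureR2Matrix <- function(modelSet, poseTable) {
  stopifnot(is(modelSet, "PoseModelSet"), is(poseTable, "PoseTable"))
  df <- as.data.frame(poseTable)
  r <- observedRmsd(poseTable)
  if (anyNA(r)) .stopf("observed RMSD required for all poses")
  structs <- sort(intersect(structureIds(modelSet), unique(df$structure_id)))
  X <- poseFeatures(poseTable)
  M <- matrix(NA_real_, length(structs), length(structs),
              dimnames = list(model = structs, data = structs))
  for (s in structs) {
    for (sp in structs) {
      rows <- df$structure_id == sp
      p <- predictSvr(modelSet[[s]], X[rows, , drop = FALSE])
      M[s, sp] <- .pearsonR2(r[rows], as.numeric(p))
    }
  }
  M
}
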