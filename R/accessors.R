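#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))
#' @export
setGeneric("structureIds", function(x) standardGeneric("structureIds"))
#' @export
setGeneric("poseKeys", function(x) standardGeneric("poseKeys"))
#' @export
setGeneric("poseFeatures", function(x) standardGeneric("poseFeatures"))
#' @export
setGeneric("observedRmsd", function(x) standardGeneric("observedRmsd"))
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))
#' @export
setGeneric("pKi", function(x) standardGeneric("pKi"))
#' @export
setGeneric("boundFlag", function(x) standardGeneric("boundFlag"))
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))
#' @export
setGeneric("setLabel<-", function(x, value) standardGeneric("setLabel<-"))

#' Construct a PoseTable
#'
#' @param data data.frame with the key columns `ligand_id, structure_id,
#'   conformer_id, run_id, pose_id`, optional `observed_rmsd`, and one or more
#'   numeric feature columns.
#' @param featureNames which columns are scoring-term features; defaults to
#'   every non-key, non-`observed_rmsd` column.
#' @return A [PoseTable-class] object.
#' @export
PoseTable <- function(data, featureNames = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(featureNames))
    featureNames <- setdiff(names(data), c(.keyCols, "observed_rmsd"))
  data$ligand_id <- as.character(data$ligand_id)
  data$structure_id <- as.character(data$structure_id)
  for (k in c("conformer_id", "run_id", "pose_id"))
    if (k %in% names(data)) data[[k]] <- as.integer(data[[k]])
  rownames(data) <- NULL
  new("PoseTable", data = data, featureNames = as.character(featureNames))
}

#' Construct a DescriptorTable
#'
#' @param values numeric matrix or data.frame; rows = ligands, columns =
#'   descriptors.
#' @param ligandIds ligand ids (defaults to rownames).
#' @return A [DescriptorTable-class] object.
#' @export
DescriptorTable <- function(values, ligandIds = rownames(values)) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  rownames(m) <- as.character(ligandIds)
  new("DescriptorTable", values = m)
}

#' Construct an AffinityTable
#'
#' @param ligandIds ligand ids.
#' @param pKi pKi values (-log10 Ki in molar).
#' @param boundFlag logical, co-crystallized ligand or not.
#' @param setLabel "train", "test" or "unassigned".
#' @return An [AffinityTable-class] object.
#' @export
AffinityTable <- function(ligandIds, pKi,
                          boundFlag = rep(FALSE, length(ligandIds)),
                          setLabel = rep("unassigned", length(ligandIds))) {
  new("AffinityTable", ligandIds = as.character(ligandIds),
      pKi = as.numeric(pKi), boundFlag = as.logical(boundFlag),
      setLabel = as.character(setLabel))
}

#' @describeIn PoseTable feature column names
#' @param x object
#' @export
setMethod("featureNames", "PoseTable", function(x) x@featureNames)
#' @describeIn PoseTable unique ligand ids
#' @export
setMethod("ligandIds", "PoseTable", function(x) unique(x@data$ligand_id))
#' @describeIn PoseTable unique structure ids
#' @export
setMethod("structureIds", "PoseTable", function(x) unique(x@data$structure_id))
#' @describeIn PoseTable the five key columns as a data.frame
#' @export
setMethod("poseKeys", "PoseTable", function(x) x@data[, .keyCols, drop = FALSE])
#' @describeIn PoseTable feature matrix (rows follow table order)
#' @export
setMethod("poseFeatures", "PoseTable",
          function(x) as.matrix(x@data[, x@featureNames, drop = FALSE]))
#' @describeIn PoseTable observed RMSD vector (NA where unlabeled)
#' @export
setMethod("observedRmsd", "PoseTable", function(x) {
  if ("observed_rmsd" %in% names(x@data)) x@data$observed_rmsd
  else rep(NA_real_, nrow(x@data))
})

setMethod("length", "PoseTable", function(x) nrow(x@data))

#' @describeIn PoseTable subset rows
#' @param i row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "PoseTable", function(x, i, j, ..., drop = FALSE) {
  new("PoseTable", data = x@data[i, , drop = FALSE], featureNames = x@featureNames)
})

#' @describeIn PoseTable coerce to data.frame
#' @export
setMethod("as.data.frame", "PoseTable", function(x, ...) {
  df <- x@data
  rownames(df) <- NULL
  df
})

setMethod("show", "PoseTable", function(object) {
  df <- object@data
  cat(sprintf("PoseTable: %d candidate pose(s), %d ligand(s), %d structure(s)\n",
              nrow(df), length(unique(df$ligand_id)),
              length(unique(df$structure_id))))
  cat(sprintf("  features (%d): %s\n", length(object@featureNames),
              paste(utils::head(object@featureNames, 6), collapse = ", ")))
  r <- observedRmsd(object)
  cat(sprintf("  observed RMSD: %d labeled row(s)\n", sum(!is.na(r))))
})

#' @describeIn DescriptorTable descriptor matrix
#' @param x object
#' @export
setMethod("descriptorMatrix", "DescriptorTable", function(x) x@values)
#' @describeIn DescriptorTable ligand ids
#' @export
setMethod("ligandIds", "DescriptorTable", function(x) rownames(x@values))
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' @describeIn DescriptorTable subset ligands (i) and descriptors (j)
#' @param i,j indices
#' @param drop,... ignored
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("DescriptorTable", values = v)
})

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d ligand(s) x %d descriptor(s); %d missing value(s)\n",
              nrow(object@values), ncol(object@values), sum(is.na(object@values))))
})

#' @describeIn AffinityTable ligand ids
#' @param x object
#' @export
setMethod("ligandIds", "AffinityTable", function(x) x@ligandIds)
#' @describeIn AffinityTable pKi values, named by ligand id
#' @export
setMethod("pKi", "AffinityTable", function(x) stats::setNames(x@pKi, x@ligandIds))
#' @describeIn AffinityTable bound/unbound flags, named by ligand id
#' @export
setMethod("boundFlag", "AffinityTable",
          function(x) stats::setNames(x@boundFlag, x@ligandIds))
#' @describeIn AffinityTable train/test labels, named by ligand id
#' @export
setMethod("setLabel", "AffinityTable",
          function(x) stats::setNames(x@setLabel, x@ligandIds))
#' @describeIn AffinityTable assign train/test labels (named or positional)
#' @param value replacement labels
#' @export
setMethod("setLabel<-", "AffinityTable", function(x, value) {
  if (!is.null(names(value))) {
    lab <- setLabel(x)
    lab[names(value)] <- value
    x@setLabel <- unname(lab)
  } else x@setLabel <- as.character(value)
  validObject(x)
  x
})
setMethod("length", "AffinityTable", function(x) length(x@ligandIds))

setMethod("show", "AffinityTable", function(object) {
  cat(sprintf("AffinityTable: %d ligand(s); pKi range [%.2f, %.2f]; %d bound; split %d/%d/%d (train/test/unassigned)\n",
              length(object@ligandIds), min(object@pKi), max(object@pKi),
              sum(object@boundFlag), sum(object@setLabel == "train"),
              sum(object@setLabel == "test"), sum(object@setLabel == "unassigned")))
})

setMethod("show", "SvrArtifact", function(object) {
  extra <- if (object@mode == "eps") sprintf("epsilon=%g", object@epsilon)
           else sprintf("nu=%g", object@nu)
  cat(sprintf("SvrArtifact (%s%s): %s-SVR, C=%g, gamma=%g, %s; %d SV, %d feature(s)\n",
              object@kind,
              if (!is.na(object@structureId)) paste0(", ", object@structureId) else "",
              object@mode, object@cost, object@gamma, extra,
              nrow(object@SV), length(object@featureNames)))
})

#' @describeIn PoseModelSet structure ids with a fitted model
#' @param x object
#' @export
setMethod("structureIds", "PoseModelSet", function(x) names(x@models))
#' @describeIn PoseModelSet shared feature list
#' @export
setMethod("featureNames", "PoseModelSet", function(x) x@featureNames)
setMethod("length", "PoseModelSet", function(x) length(x@models))

#' @describeIn PoseModelSet extract one structure's model
#' @param i structure id or index
#' @param j,drop,... ignored
#' @export
setMethod("[[", "PoseModelSet", function(x, i, j, ...) x@models[[i]])

setMethod("show", "PoseModelSet", function(object) {
  cat(sprintf("PoseModelSet: %d per-structure pose-RMSD model(s)\n",
              length(object@models)))
  if (nrow(object@meta)) {
    cat(sprintf("  q2cv: %s\n",
                paste(sprintf("%s=%.2f", object@meta$structure_id,
                              object@meta$q2cv), collapse = " ")))
  }
})

#' Training metadata of a PoseModelSet
#'
#' @param x a [PoseModelSet-class].
#' @return data.frame with one row per structure: n, q2cv, trainR2.
#' @export
poseModelMeta <- function(x) x@meta
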