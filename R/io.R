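#' Read a pose table from CSV/TSV
#'
#' The file must carry the five key columns `ligand_id, structure_id,
#' conformer_id, run_id, pose_id`; every remaining numeric column except the
#' optional `observed_rmsd` is taken as a scoring-term feature. Empty fields
#' are the missing-value marker.
#'
#' @param path file path.
#' @param dialect "csv" or "tsv"; default guessed from the file extension.
#' @return A [PoseTable-class].
#' @export
readPoseTable <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("pose table file not found: %s", path)
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "")
  miss <- setdiff(.keyCols, names(df))
  if (length(miss))
    .stopf("pose table schema error: missing key column(s) %s",
           paste(miss, collapse = ", "))
  feat <- setdiff(names(df), c(.keyCols, "observed_rmsd"))
  if (!length(feat)) .stopf("pose table schema error: no feature columns")
  for (f in feat) {
    if (!is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))) & !is.na(df[[f]]))[1L]
      .stopf("non-numeric feature value in column '%s', row %d", f, bad)
    }
  }
  ks <- .keyString(df)
  if (anyDuplicated(ks))
    .stopf("pose table integrity error: duplicate key at row %d",
           which(duplicated(ks))[1L])
  PoseTable(df, featureNames = feat)
}

#' Write a pose table to CSV/TSV
#'
#' Missing values are written as empty fields; `readPoseTable()` on the
#' output returns an equal table.
#'
#' @param table a [PoseTable-class].
#' @param path output path.
#' @param dialect "csv" or "tsv"; default guessed from the extension.
#' @export
writePoseTable <- function(table, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(table, "PoseTable"))
  validObject(table)
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "\t" else ",")
  utils::write.table(as.data.frame(table), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-ligand descriptor table from CSV
#'
#' @param path CSV with a `ligand_id` column plus numeric descriptor columns;
#'   empty fields are missing values.
#' @return A [DescriptorTable-class].
#' @export
readDescriptorTable <- function(path) {
  if (!file.exists(path)) .stopf("descriptor table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  if (!"ligand_id" %in% names(df))
    .stopf("descriptor table schema error: missing 'ligand_id'")
  ids <- as.character(df$ligand_id)
  m <- as.matrix(df[, setdiff(names(df), "ligand_id"), drop = FALSE])
  storage.mode(m) <- "double"
  DescriptorTable(m, ligandIds = ids)
}

#' @rdname readDescriptorTable
#' @param table a [DescriptorTable-class].
#' @export
writeDescriptorTable <- function(table, path) {
  stopifnot(is(table, "DescriptorTable"))
  df <- data.frame(ligand_id = ligandIds(table),
                   as.data.frame(descriptorMatrix(table)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a per-ligand affinity table from CSV
#'
#' Expects `ligand_id` plus either a `ki` column (with `kiUnits` "M" or "nM")
#' or a `pki` column (`kiUnits = "pKi"`). pKi is computed as -log10(Ki in
#' molar). Optional columns `bound_flag` (0/1 or logical) and `set_label`
#' are carried through.
#'
#' @param path CSV path.
#' @param kiUnits "M", "nM" or "pKi".
#' @return An [AffinityTable-class].
#' @export
readAffinityTable <- function(path, kiUnits = c("M", "nM", "pKi")) {
  kiUnits <- match.arg(kiUnits)
  if (!file.exists(path)) .stopf("affinity table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!"ligand_id" %in% names(df))
    .stopf("affinity table schema error: missing 'ligand_id'")
  if (kiUnits == "pKi") {
    if (!"pki" %in% names(df)) .stopf("kiUnits='pKi' requires a 'pki' column")
    pki <- as.numeric(df$pki)
  } else {
    if (!"ki" %in% names(df)) .stopf("kiUnits='%s' requires a 'ki' column", kiUnits)
    ki <- as.numeric(df$ki)
    if (any(!is.finite(ki)) || any(ki <= 0))
      .stopf("Ki values must be positive and finite")
    molar <- if (kiUnits == "nM") ki * 1e-9 else ki
    pki <- -log10(molar)
  }
  AffinityTable(
    ligandIds = df$ligand_id, pKi = pki,
    boundFlag = if ("bound_flag" %in% names(df)) as.logical(df$bound_flag)
                else rep(FALSE, nrow(df)),
    setLabel = if ("set_label" %in% names(df)) df$set_label
               else rep("unassigned", nrow(df)))
}

#' @rdname readAffinityTable
#' @param table an [AffinityTable-class].
#' @export
writeAffinityTable <- function(table, path) {
  stopifnot(is(table, "AffinityTable"))
  df <- data.frame(ligand_id = ligandIds(table), pki = unname(pKi(table)),
                   bound_flag = as.integer(unname(boundFlag(table))),
                   set_label = unname(setLabel(table)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Geometric pose RMSD in the fixed protein frame
#'
#' Root-mean-square deviation between two conformations of the same molecule,
#' with atom correspondence by position and no re-superposition: docking pose
#' RMSD is measured in the frame of the (fixed) receptor, so rigid alignment
#' would hide placement error.
#'
#' @param coordsA,coordsB numeric n x 3 matrices of Cartesian coordinates
#'   (Angstrom), same atom order.
#' @return RMSD in Angstrom.
#' @export
computePoseRmsd <- function(coordsA, coordsB) {
  a <- as.matrix(coordsA); b <- as.matrix(coordsB)
  if (nrow(a) == 0L) .stopf("empty coordinate set")
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    .stopf("coordinate sets must be equal-size n x 3 matrices")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Read ligand coordinates from an SDF file
#'
#' Extracts the atom coordinate block of every molecule in an SDF/MOL file,
#' optionally restricted to heavy atoms (the convention used for pose RMSD
#' here). Parsing is delegated to ChemmineR.
#'
#' @param path SDF file.
#' @param heavyOnly drop hydrogens (default TRUE).
#' @return Named list of n x 3 coordinate matrices (Angstrom).
#' @export
readSdfCoords <- function(path, heavyOnly = TRUE) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    .stopf("readSdfCoords requires the ChemmineR package")
  if (!file.exists(path)) .stopf("SDF file not found: %s", path)
  sdf <- ChemmineR::read.SDFset(path)
  out <- lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    m <- ab[, 1:3, drop = FALSE]
    if (heavyOnly) {
      elem <- sub("_.*$", "", rownames(ab))
      m <- m[elem != "H", , drop = FALSE]
    }
    colnames(m) <- c("x", "y", "z")
    m
  })
  ids <- unlist(ChemmineR::sdfid(sdf))
  names(out) <- if (length(ids) == length(out)) ids else seq_along(out)
  out
}

.ARTIFACT_VERSION <- "dockrescore-svr/1"

#' Save / load a fitted SVR artifact
#'
#' Artifacts are versioned JSON documents carrying every slot of the
#' [SvrArtifact-class] at full double precision (17 significant digits), so a
#' round-trip reproduces predictions bit-for-bit.
#'
#' @param artifact an [SvrArtifact-class].
#' @param path JSON file path.
#' @export
saveModel <- function(artifact, path) {
  stopifnot(is(artifact, "SvrArtifact"))
  validObject(artifact)
  doc <- list(
    version = .ARTIFACT_VERSION,
    kind = artifact@kind, structure_id = artifact@structureId,
    mode = artifact@mode, C = artifact@cost, gamma = artifact@gamma,
    epsilon = artifact@epsilon, nu = artifact@nu,
    feature_names = artifact@featureNames,
    center = artifact@center, scale = artifact@scale,
    sv = artifact@SV, coefs = artifact@coefs, rho = artifact@rho,
    meta = artifact@meta)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname saveModel
#' @param expectKind optionally require "pose" or "score"; a mismatch errors.
#' @return `loadModel`: the restored [SvrArtifact-class].
#' @export
loadModel <- function(path, expectKind = NULL) {
  if (!file.exists(path)) .stopf("model file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .stopf("corrupted model file: %s",
                                             conditionMessage(e)))
  if (is.null(doc$version) || !identical(doc$version, .ARTIFACT_VERSION))
    .stopf("incompatible model artifact version '%s' (expected '%s')",
           if (is.null(doc$version)) "<none>" else doc$version, .ARTIFACT_VERSION)
  if (!is.null(expectKind) && !identical(doc$kind, expectKind))
    .stopf("model kind mismatch: found '%s', expected '%s'", doc$kind, expectKind)
  sv <- matrix(as.numeric(doc$sv), nrow = length(doc$coefs),
               ncol = length(doc$feature_names))
  new("SvrArtifact", kind = doc$kind,
      structureId = if (is.null(doc$structure_id)) NA_character_
                    else as.character(doc$structure_id),
      mode = doc$mode, cost = doc$C, gamma = doc$gamma,
      epsilon = if (is.null(doc$epsilon)) NA_real_ else doc$epsilon,
      nu = if (is.null(doc$nu)) NA_real_ else doc$nu,
      featureNames = doc$feature_names,
      center = as.numeric(doc$center), scale = as.numeric(doc$scale),
      SV = sv, coefs = as.numeric(doc$coefs), rho = doc$rho,
      version = doc$version,
      meta = if (is.null(doc$meta)) list() else as.list(doc$meta))
}
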