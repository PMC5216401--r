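#' Full regression validation report
#'
#' Computes the external-validation statistics used throughout QSAR model
#' assessment for an observed/predicted pair: squared Pearson correlation r2,
#' error summaries (RMSE, MAE, residual standard deviation s, maximum
#' absolute residual), the through-origin slopes and determination
#' coefficients of Golbraikh and Tropsha (k, k', r0^2, r0'^2), Roy's rm2
#' family, and Lin's concordance correlation coefficient (CCC, population
#' moments).
#'
#' Definitions (y observed, p predicted, n = length):
#' \itemize{
#'   \item k = sum(y*p)/sum(p^2), k' = sum(y*p)/sum(y^2)
#'   \item r0^2 = 1 - sum((y - k*p)^2)/sum((y - mean(y))^2);
#'     r0'^2 = 1 - sum((p - k'*y)^2)/sum((p - mean(p))^2)
#'   \item rm2 = r2 * (1 - sqrt(|r2 - r0^2|)); rm2' analogously with r0'^2;
#'     rm2avg and deltaRm2 are their mean and absolute difference
#'   \item CCC = 2*cov(y,p) / (var(y) + var(p) + (mean(y) - mean(p))^2)
#'     with population (biased) moments
#' }
#' The absolute value under the rm2 radical keeps the statistic defined when
#' r0^2 exceeds r2.
#'
#' @param y observed values (length >= 3, non-constant).
#' @param predicted predicted values.
#' @param q2cv optional cross-validated q2 to attach (see
#'   [q2CrossValidation()]).
#' @return A list of class `"RegressionReport"`.
#' @export
regressionReport <- function(y, predicted, q2cv = NA_real_) {
  p <- as.numeric(predicted); y <- as.numeric(y)
  if (length(y) != length(p)) .stopf("length mismatch: %d vs %d", length(y), length(p))
  n <- length(y)
  if (n < 3) .stopf("need at least 3 observations")
  if (stats::sd(y) == 0) .stopf("constant observed values")
  res <- y - p
  r2 <- .pearsonR2(y, p)
  k <- sum(y * p) / sum(p^2)
  kPrime <- sum(y * p) / sum(y^2)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  r02Prime <- 1 - sum((p - kPrime * y)^2) / sum((p - mean(p))^2)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r02)))
  rm2Prime <- r2 * (1 - sqrt(abs(r2 - r02Prime)))
  covYP <- mean((y - mean(y)) * (p - mean(p)))
  ccc <- 2 * covYP /
    (mean((y - mean(y))^2) + mean((p - mean(p))^2) + (mean(y) - mean(p))^2)
  out <- list(
    n = n, r2 = r2, q2 = r2, q2f = 1 - sum(res^2) / sum((y - mean(y))^2),
    q2cv = q2cv,
    rmse = sqrt(mean(res^2)), mae = mean(abs(res)), s = stats::sd(res),
    deltaMax = max(abs(res)),
    k = k, kPrime = kPrime, r02 = r02, r02Prime = r02Prime,
    rm2 = rm2, rm2Prime = rm2Prime, rm2Avg = (rm2 + rm2Prime) / 2,
    deltaRm2 = abs(rm2 - rm2Prime), ccc = ccc)
  class(out) <- c("RegressionReport", "list")
  out
}

#' @export
print.RegressionReport <- function(x, ...) {
  cat(sprintf("RegressionReport (n = %d)\n", x$n))
  cat(sprintf("  r2 = %.4f  q2(F) = %.4f  q2cv = %s\n", x$r2, x$q2f,
              ifelse(is.na(x$q2cv), "NA", sprintf("%.4f", x$q2cv))))
  cat(sprintf("  RMSE = %.4f  MAE = %.4f  s = %.4f  |res|max = %.4f\n",
              x$rmse, x$mae, x$s, x$deltaMax))
  cat(sprintf("  k = %.4f  k' = %.4f  r0^2 = %.4f  r0'^2 = %.4f\n",
              x$k, x$kPrime, x$r02, x$r02Prime))
  cat(sprintf("  rm2 = %.4f  rm2' = %.4f  <rm2> = %.4f  drm2 = %.4f  CCC = %.4f\n",
              x$rm2, x$rm2Prime, x$rm2Avg, x$deltaRm2, x$ccc))
  invisible(x)
}

#' Cross-validated predictive coefficient q2cv
#'
#' q2cv = 1 - PRESS / sum((y - mean(y))^2) from out-of-fold predictions,
#' with a seeded fold assignment stratified by response quantile.
#'
#' @param X feature matrix.
#' @param y response.
#' @param trainer function(Xtrain, ytrain) returning a prediction function
#'   function(Xnew) -> numeric.
#' @param folds number of folds (default 10; `folds = length(y)` is
#'   leave-one-out).
#' @param seed fold-assignment seed.
#' @return q2cv (scalar).
#' @export
q2CrossValidation <- function(X, y, trainer, folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < folds) .stopf("n = %d is smaller than folds = %d", n, folds)
  fold <- .makeFolds(y, folds, seed)
  pred <- rep(NA_real_, n)
  for (f in unique(fold)) {
    tr <- fold != f
    fit <- trainer(X[tr, , drop = FALSE], y[tr])
    pred[!tr] <- fit(X[!tr, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

.criteriaDefs <- function() {
  list(
    list(id = "cv_q2", label = "q2cv (train) > 0.5",
         fn = function(tr, te) list(value = tr$q2cv, pass = isTRUE(tr$q2cv > 0.5))),
    list(id = "test_r2", label = "r2 (test) > 0.6",
         fn = function(tr, te) list(value = te$r2, pass = isTRUE(te$r2 > 0.6))),
    list(id = "r0_ratio", label = "(r2-r0^2)/r2 < 0.1 or (r2-r0'^2)/r2 < 0.1 (test)",
         fn = function(tr, te) {
           v <- min((te$r2 - te$r02) / te$r2, (te$r2 - te$r02Prime) / te$r2)
           list(value = v, pass = isTRUE(v < 0.1))
         }),
    list(id = "slope", label = "0.85 <= k <= 1.15 or 0.85 <= k' <= 1.15 (test)",
         fn = function(tr, te) {
           pass <- (te$k >= 0.85 && te$k <= 1.15) ||
                   (te$kPrime >= 0.85 && te$kPrime <= 1.15)
           list(value = te$k, pass = isTRUE(pass))
         }),
    list(id = "r0_diff", label = "|r0^2 - r0'^2| < 0.3 (test)",
         fn = function(tr, te) {
           v <- abs(te$r02 - te$r02Prime)
           list(value = v, pass = isTRUE(v < 0.3))
         }),
    list(id = "rm2", label = "<rm2> > 0.5 and drm2 < 0.2 (test)",
         fn = function(tr, te)
           list(value = te$rm2Avg,
                pass = isTRUE(te$rm2Avg > 0.5 && te$deltaRm2 < 0.2))),
    list(id = "ccc", label = "CCC > 0.85 (test)",
         fn = function(tr, te) list(value = te$ccc, pass = isTRUE(te$ccc > 0.85))),
    list(id = "test_q2", label = "q2 (test, F-form) > 0.5",
         fn = function(tr, te) list(value = te$q2f, pass = isTRUE(te$q2f > 0.5)))
  )
}

#' External-validation criteria battery
#'
#' Evaluates the stringent pass/fail validation criteria of the
#' Golbraikh-Tropsha / Ojha / Roy / Chirico-Gramatica family against a
#' training-set and a test-set [regressionReport()]: cross-validated q2cv >
#' 0.5; test r2 > 0.6; closeness of the through-origin coefficients
#' ((r2-r0^2)/r2 < 0.1, either direction); through-origin slope within
#' [0.85, 1.15] (either direction); |r0^2 - r0'^2| < 0.3; rm2 average > 0.5
#' with difference < 0.2; CCC > 0.85; and the F-form external q2 > 0.5.
#'
#' @param trainReport,testReport `"RegressionReport"` lists (or any list
#'   carrying the needed fields).
#' @return data.frame of class `"CriteriaReport"`: criterion, description,
#'   value, pass; attribute `"overall"` is TRUE iff all criteria pass.
#' @export
criteriaBattery <- function(trainReport, testReport) {
  defs <- .criteriaDefs()
  need <- c("r2", "r02", "r02Prime", "k", "kPrime", "rm2Avg", "deltaRm2",
            "ccc", "q2f")
  miss <- setdiff(need, names(testReport))
  if (length(miss))
    .stopf("incomplete test report: missing %s", paste(miss, collapse = ", "))
  rows <- lapply(defs, function(d) {
    r <- d$fn(trainReport, testReport)
    data.frame(criterion = d$id, description = d$label,
               value = r$value, pass = r$pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall") <- all(out$pass)
  class(out) <- c("CriteriaReport", "data.frame")
  out
}

#' @export
print.CriteriaReport <- function(x, ...) {
  df <- as.data.frame(x)
  df$verdict <- ifelse(df$pass, "x", "-")
  print.data.frame(df[, c("criterion", "description", "value", "verdict")],
                   row.names = FALSE, digits = 4)
  cat(sprintf("overall: %s\n", if (attr(x, "overall")) "PASS" else "FAIL"))
  invisible(x)
}

#' Confusion matrix for top-pose selection
#'
#' A candidate is actual-positive when it attains its group's minimum
#' observed RMSD (all candidates tied at the minimum count as positive) and
#' predicted-positive when it is the group's selected candidate; counts are
#' aggregated over groups.
#'
#' @param selections data.frame of selected candidate keys, one row per
#'   group (as returned by [selectTopPose()]).
#' @param poseTable a [PoseTable-class] with observed RMSD for all candidates.
#' @param groupBy grouping key column(s), default `"ligand_id"`.
#' @return named integer vector (TP, FP, FN, TN) of class
#'   `"ConfusionMatrix"`.
#' @export
poseSelectionConfusion <- function(selections, poseTable,
                                   groupBy = "ligand_id") {
  df <- as.data.frame(poseTable)
  if (any(is.na(df$observed_rmsd)))
    .stopf("observed RMSD required for every candidate")
  grp <- interaction(df[groupBy], drop = TRUE)
  selKey <- .keyString(selections)
  key <- .keyString(df)
  tp <- fp <- fn <- tn <- 0L
  for (g in levels(grp)) {
    idx <- which(grp == g)
    sel <- key[idx] %in% selKey
    if (!any(sel)) .stopf("group '%s' has no selection", g)
    rmin <- min(df$observed_rmsd[idx])
    actual <- df$observed_rmsd[idx] <= rmin
    tp <- tp + sum(sel & actual); fp <- fp + sum(sel & !actual)
    fn <- fn + sum(!sel & actual); tn <- tn + sum(!sel & !actual)
  }
  out <- c(TP = tp, FP = fp, FN = fn, TN = tn)
  class(out) <- "ConfusionMatrix"
  out
}

#' Cooper statistics and Kubat's G-mean from a confusion matrix
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
#' (0, flagged, when a marginal is empty), G-mean =
#' sqrt(sensitivity * specificity).
#'
#' @param cm named vector or list with TP, FP, FN, TN (non-negative).
#' @return list of class `"ClassificationReport"`.
#' @export
classificationReport <- function(cm) {
  cm <- unclass(cm)
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
  if (any(c(tp, fp, fn, tn) < 0)) .stopf("negative confusion-matrix counts")
  total <- tp + fp + fn + tn
  if (total == 0) .stopf("empty confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mccFlag <- den == 0
  out <- list(sensitivity = sens, specificity = spec,
              accuracy = (tp + tn) / total,
              mcc = if (mccFlag) 0 else (tp * tn - fp * fn) / den,
              mccUndefined = mccFlag,
              gmean = sqrt(sens * spec))
  class(out) <- c("ClassificationReport", "list")
  out
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.3f  specificity %.3f  accuracy %.3f  MCC %.3f%s  G-mean %.3f\n",
    x$sensitivity, x$specificity, x$accuracy, x$mcc,
    if (x$mccUndefined) " (undefined, reported 0)" else "", x$gmean))
  invisible(x)
}
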