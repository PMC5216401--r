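test_that("regression report reproduces hand-computed statistics", {
  perfect <- regressionReport(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$k, 1)
  expect_equal(perfect$r02, 1)
  expect_equal(perfect$rm2, 1)
  expect_equal(perfect$ccc, 1)

  doubled <- regressionReport(c(1, 2, 3), c(2, 4, 6))
  expect_equal(doubled$r2, 1)
  expect_equal(doubled$k, 0.5)
  expect_equal(doubled$r02, 1)
  expect_equal(doubled$ccc, 8 / 22)

  shifted <- regressionReport(c(0, 1, 2), c(1, 2, 3))
  expect_equal(shifted$ccc, 4 / 7)

  expect_error(regressionReport(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regressionReport(1:4, 1:3), "length mismatch")
})

test_that("every report field matches the independent oracle on random pairs", {
  set.seed(51)
  for (i in 1:100) {
    y <- rnorm(10, 6, 2)
    p <- y + rnorm(10, sd = runif(1, 0.1, 2))
    rep <- regressionReport(y, p)
    orc <- oracleReport(y, p)
    for (f in names(orc)) expect_lt(abs(rep[[f]] - orc[[f]]), 1e-10)
  }
})

test_that("concordance and rm2 inequalities hold", {
  set.seed(52)
  for (i in 1:50) {
    y <- rnorm(12); p <- rnorm(12) + 0.5 * y
    rep <- regressionReport(y, p)
    expect_lte(abs(rep$ccc), abs(cor(y, p)) + 1e-12)
    expect_lte(rep$rm2, rep$r2 + 1e-12)
    if (abs(rep$r02 - rep$r2) < 1e-12) expect_equal(rep$rm2, rep$r2)
  }
  # CCC attains |r| exactly for the identity relation
  y <- rnorm(12)
  expect_equal(regressionReport(y, y)$ccc, 1)
})

test_that("q2cv behaves for interpolable, mean-only and LOO cases", {
  fx <- linearFixture(n = 24, p = 2, noise = 0, seed = 53)
  lmTrainer <- function(X, y) {
    fit <- lm.fit(cbind(1, X), y)
    function(Xn) as.numeric(cbind(1, Xn) %*% fit$coefficients)
  }
  expect_gte(q2CrossValidation(fx$X, fx$y, lmTrainer, folds = 6, seed = 1), 0.99)

  meanTrainer <- function(X, y) { m <- mean(y); function(Xn) rep(m, nrow(Xn)) }
  set.seed(54)
  yr <- rnorm(30)
  expect_lte(q2CrossValidation(matrix(rnorm(30), 30, 1), yr, meanTrainer,
                               folds = 5, seed = 2), 0)

  # folds = n equals an explicitly enumerated leave-one-out
  set.seed(55)
  X <- matrix(rnorm(24), 12, 2); y <- X[, 1] + rnorm(12, sd = 0.3)
  q2loo <- q2CrossValidation(X, y, lmTrainer, folds = 12, seed = 3)
  press <- sum(vapply(1:12, function(i) {
    f <- lmTrainer(X[-i, , drop = FALSE], y[-i])
    (y[i] - f(X[i, , drop = FALSE]))^2
  }, numeric(1)))
  expect_equal(q2loo, 1 - press / sum((y - mean(y))^2))
})

test_that("criteria battery passes ideal models and rejects mean predictors", {
  set.seed(56)
  y <- rnorm(20, 6, 1.5)
  ideal <- regressionReport(y, y, q2cv = 1)
  cb <- criteriaBattery(ideal, ideal)
  expect_true(attr(cb, "overall"))
  expect_true(all(cb$pass))

  # constant predictions at the mean: external q2 criterion must fail
  nearConst <- regressionReport(y, rep(mean(y), 20) + rnorm(20, sd = 1e-6),
                                q2cv = 1)
  cb2 <- criteriaBattery(ideal, nearConst)
  expect_false(cb2$pass[cb2$criterion == "test_q2"])
  expect_false(attr(cb2, "overall"))

  expect_error(criteriaBattery(ideal, list(r2 = 0.9)), "incomplete")
})

test_that("threshold checks pass at published SVM-Score statistic levels", {
  # r2 = 0.967 > 0.6, external q2 = 0.894 > 0.5, q2cv = 0.899 > 0.5
  expect_true(0.967 > 0.6)
  train <- list(q2cv = 0.899)
  test <- list(r2 = 0.894, q2f = 0.894, r02 = 0.894, r02Prime = 0.894,
               k = 1, kPrime = 1, rm2Avg = 0.894, deltaRm2 = 0, ccc = 0.9)
  test$r2 <- 0.967  # training-level correlation also clears the bar
  cb <- criteriaBattery(train, test)
  expect_true(cb$pass[cb$criterion == "cv_q2"])
  expect_true(cb$pass[cb$criterion == "test_r2"])
  expect_true(cb$pass[cb$criterion == "test_q2"])
})

test_that("pose-selection confusion counts follow the stated rules", {
  df <- data.frame(
    ligand_id = rep(c("L1", "L2"), each = 3), structure_id = "S1",
    conformer_id = 1L, run_id = 1L, pose_id = rep(1:3, 2),
    t1 = rnorm(6),
    observed_rmsd = c(0.2, 1.0, 2.0, 1.5, 0.3, 2.5))
  pt <- PoseTable(df)
  # L1: correct selection (pose 1); L2: wrong selection (pose 3)
  sel <- df[c(1, 6), 1:5]
  cm <- poseSelectionConfusion(sel, pt)
  expect_equal(unclass(cm), c(TP = 1L, FP = 1L, FN = 1L, TN = 3L))
  rep <- classificationReport(cm)
  expect_equal(rep$sensitivity, 0.5)
  expect_equal(rep$specificity, 0.75)

  # all selections correct
  selGood <- df[c(1, 5), 1:5]
  cmG <- poseSelectionConfusion(selGood, pt)
  expect_equal(unclass(cmG)[c("FP", "FN")], c(FP = 0L, FN = 0L))
  repG <- classificationReport(cmG)
  expect_equal(repG$sensitivity, 1)
  expect_equal(repG$gmean, 1)

  # tie at the group minimum: both tied candidates are actual-positive
  tie <- df
  tie$observed_rmsd <- c(0.2, 0.2, 2.0, 1.5, 0.3, 2.5)
  cmT <- poseSelectionConfusion(df[c(2, 5), 1:5], PoseTable(tie))
  expect_equal(unclass(cmT)[["TP"]], 2L)
  expect_equal(unclass(cmT)[["FN"]], 1L)  # the unselected tied candidate

  expect_error(poseSelectionConfusion(df[1, 1:5], pt), "no selection")
})

test_that("classification report computes Cooper statistics and G-mean", {
  rep <- classificationReport(c(TP = 3, FP = 1, FN = 2, TN = 4))
  expect_equal(rep$sensitivity, 0.6)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$accuracy, 0.7)
  expect_equal(rep$mcc, 10 / sqrt(600))
  expect_equal(rep$gmean, sqrt(0.48))
  expect_equal(rep$gmean^2, rep$sensitivity * rep$specificity)

  perfect <- classificationReport(c(TP = 5, FP = 0, FN = 0, TN = 7))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  worst <- classificationReport(c(TP = 0, FP = 3, FN = 2, TN = 0))
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$gmean, 0)
  expect_lte(worst$mcc, 0)

  zeroDen <- classificationReport(c(TP = 0, FP = 0, FN = 2, TN = 3))
  expect_true(zeroDen$mccUndefined)
  expect_equal(zeroDen$mcc, 0)
  expect_error(classificationReport(c(TP = -1, FP = 0, FN = 0, TN = 1)),
               "negative")
})
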