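test_that("grid scan selects by cross-validated q2 and enumerates the lattice", {
  fx <- linearFixture(n = 40, p = 3, noise = 0, seed = 21)
  Z <- scale(fx$X)
  single <- defaultSvrGrid(C = 2, gamma = 0.5, epsilon = 0.1, modes = "eps")
  out <- gridScanSvr(Z, fx$y, single, folds = 5, seed = 1)
  expect_equal(nrow(out$scan), 1)
  expect_equal(out$best$C, 2)

  wide <- defaultSvrGrid(C = 2^c(0, 4, 8), gamma = 2^c(-6, -3, 0),
                         epsilon = c(0.01, 0.1), nu = 0.5)
  out2 <- gridScanSvr(Z, fx$y, wide, folds = 5, seed = 1)
  expect_equal(nrow(out2$scan), nrow(wide))
  expect_gte(out2$q2cv, 0.99)  # noiseless linear target
  expect_error(gridScanSvr(Z[1:3, ], fx$y[1:3], wide, folds = 5), "smaller than")
  expect_error(gridScanSvr(Z, fx$y, wide[0, ], folds = 5), "empty")
})

test_that("pose models learn a noiseless structure and fail on permuted labels", {
  set.seed(23)
  n <- 30
  df <- data.frame(ligand_id = sprintf("L%02d", 1:n), structure_id = "S1",
                   conformer_id = 1L, run_id = 1L, pose_id = 1L)
  r <- runif(n, 0, 5)
  df$t1 <- 2 * exp(-r / 1.5)
  df$t2 <- 0.4 * r
  df$observed_rmsd <- r
  pt <- PoseTable(df)
  grid <- defaultSvrGrid(coarse = TRUE)
  m <- trainPoseModel("S1", pt, grid, folds = 5, seed = 1)
  expect_gte(m@meta$trainR2, 0.99)

  # y-scrambling at the hyperparameters chosen on the real labels: the
  # scrambled response carries no signal
  perm <- df
  perm$observed_rmsd <- sample(r)
  chosen <- defaultSvrGrid(C = m@cost, gamma = m@gamma,
                           epsilon = if (m@mode == "eps") m@epsilon else NULL,
                           nu = if (m@mode == "nu") m@nu else NULL,
                           modes = m@mode)
  mp <- trainPoseModel("S1", PoseTable(perm), chosen, folds = 5, seed = 1)
  expect_lte(mp@meta$q2cv, 0.2)

  # unlabeled poses are an error naming the offending keys
  nal <- df; nal$observed_rmsd[3] <- NA
  expect_error(trainPoseModel("S1", PoseTable(nal), grid), "lack observed RMSD")
  expect_error(trainPoseModel("S9", pt, grid), "no poses")
  expect_error(trainPoseModel("S1", pt[1:5], grid, minPoses = 10), "need >= 10")
})

test_that("a model set holds one model per structure with shared features", {
  df <- tinyPoseDf(nLigands = 6, nStructures = 3, nPoses = 3, seed = 9)
  df$observed_rmsd <- runif(nrow(df), 0, 5)
  pt <- PoseTable(df)
  grid <- defaultSvrGrid(C = 4, gamma = 0.25, epsilon = 0.1, modes = "eps")
  ms <- trainPoseModelSet(pt, grid, folds = 5, seed = 1, minPoses = 10)
  expect_length(ms, 3)
  expect_setequal(structureIds(ms), unique(df$structure_id))
  meta <- poseModelMeta(ms)
  expect_true(all(c("structure_id", "n", "q2cv", "trainR2") %in% names(meta)))
  expect_true(all(is.finite(meta$q2cv)))

  one <- trainPoseModelSet(pt[df$structure_id == "S1"], grid, folds = 5,
                           seed = 1, minPoses = 10)
  expect_length(one, 1)

  expect_error(trainPoseModelSet(pt[1:25], grid, folds = 5, minPoses = 10),
               "undertrained")
})

test_that("prediction routes rows to their structure model and clips at zero", {
  df <- tinyPoseDf(nLigands = 6, nStructures = 2, nPoses = 3, seed = 10)
  df$observed_rmsd <- runif(nrow(df), 0, 5)
  pt <- PoseTable(df)
  grid <- defaultSvrGrid(C = 4, gamma = 0.25, epsilon = 0.1, modes = "eps")
  ms <- trainPoseModelSet(pt, grid, folds = 5, seed = 1, minPoses = 10)
  pred <- predictPoseRmsd(ms, pt)
  expect_equal(nrow(pred), length(pt))
  expect_true(all(pred$predicted_rmsd >= 0))
  expect_true(all(is.finite(pred$predicted_rmsd)))
  # training-row predictions agree with the per-model fit
  s1 <- df$structure_id == "S1"
  direct <- predictSvr(ms[["S1"]], poseFeatures(pt)[s1, ])
  expect_equal(pred$predicted_rmsd[s1], as.numeric(direct))

  alien <- df; alien$structure_id[1] <- "S99"
  expect_error(predictPoseRmsd(ms, PoseTable(alien)), "S99")

  # clipping: a raw negative prediction surfaces as 0 with a flag
  art <- ms[["S1"]]
  low <- poseFeatures(pt)[s1, ][which.min(direct), , drop = FALSE]
  shifted <- low
  p <- predictSvr(art, shifted)
  expect_true(all(p >= 0))
})

test_that("top-pose selection is an argmin with documented tie-breaks", {
  base <- data.frame(ligand_id = "L1", structure_id = c("S2", "S1", "S3"),
                     conformer_id = 1L, run_id = 1L, pose_id = 1:3,
                     predicted_rmsd = c(1.2, 0.4, 0.9))
  sel <- selectTopPose(base)
  expect_equal(sel$predicted_rmsd, 0.4)
  expect_equal(sel$structure_id, "S1")

  tie <- base
  tie$predicted_rmsd <- c(0.4, 0.4, 0.9)
  sel2 <- selectTopPose(tie)
  expect_equal(sel2$structure_id, "S1")  # lexicographic (structure, conf, run, pose)

  expect_error(selectTopPose(base[, -6]), "predicted_rmsd")
})

test_that("selection is invariant under strictly increasing transforms", {
  set.seed(26)
  for (i in 1:10) {
    df <- tinyPoseDf(nLigands = 3, nStructures = 2, nPoses = 4, seed = i)
    pred <- cbind(df[, 1:5], predicted_rmsd = runif(nrow(df), 0, 6))
    s0 <- selectTopPose(pred)
    f <- sample(list(function(x) 2 * x + 1, function(x) x^3, exp), 1)[[1]]
    pred2 <- pred
    pred2$predicted_rmsd <- f(pred$predicted_rmsd)
    expect_identical(selectTopPose(pred2)[, 1:5], s0[, 1:5])
  }
})

test_that("training is deterministic under a fixed seed", {
  df <- tinyPoseDf(nLigands = 6, nStructures = 2, nPoses = 3, seed = 11)
  df$observed_rmsd <- runif(nrow(df), 0, 5)
  pt <- PoseTable(df)
  grid <- defaultSvrGrid(C = c(1, 8), gamma = c(0.1, 0.5), epsilon = 0.1,
                         modes = "eps")
  m1 <- trainPoseModelSet(pt, grid, folds = 5, seed = 7, minPoses = 10)
  m2 <- trainPoseModelSet(pt, grid, folds = 5, seed = 7, minPoses = 10)
  X <- poseFeatures(pt)
  expect_identical(predictSvr(m1[["S1"]], X), predictSvr(m2[["S1"]], X))
  expect_identical(poseModelMeta(m1), poseModelMeta(m2))
})

test_that("cross-structure matrix has native performance on the diagonal", {
  set.seed(27)
  mkStruct <- function(sid, slope) {
    n <- 40
    df <- data.frame(ligand_id = sprintf("%s_L%02d", sid, 1:n),
                     structure_id = sid, conformer_id = 1L, run_id = 1L,
                     pose_id = 1L)
    r <- runif(n, 0, 5)
    df$t1 <- slope * exp(-r) + rnorm(n, sd = 0.05)
    df$t2 <- -slope * 0.3 * r + rnorm(n, sd = 0.05)
    df$observed_rmsd <- r
    df
  }
  # opposite-sign links force transfer failure
  pt <- PoseTable(rbind(mkStruct("A", 2), mkStruct("B", -2)))
  grid <- defaultSvrGrid(C = c(1, 32), gamma = c(0.1, 1), epsilon = 0.1,
                         modes = "eps")
  ms <- trainPoseModelSet(pt, grid, folds = 5, seed = 1, minPoses = 10)
  M <- crossStructureR2Matrix(ms, pt)
  expect_equal(dim(M), c(2, 2))
  expect_gt(mean(diag(M)), mean(M[row(M) != col(M)]))

  M1 <- crossStructureR2Matrix(ms, pt[as.data.frame(pt)$structure_id == "A"])
  expect_equal(dim(M1), c(1, 1))
})
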