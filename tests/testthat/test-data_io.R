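test_that("pose tables round-trip through CSV and TSV", {
  set.seed(11)
  for (i in 1:20) {
    df <- tinyPoseDf(nLigands = sample(1:3, 1), nStructures = sample(1:3, 1),
                     nPoses = sample(1:4, 1), seed = i)
    if (i %% 3 == 0) df$observed_rmsd[1] <- NA  # missing label survives
    pt <- PoseTable(df)
    for (ext in c("csv", "tsv")) {
      f <- tempfile(fileext = paste0(".", ext))
      writePoseTable(pt, f)
      back <- readPoseTable(f)
      expect_equal(as.data.frame(back), as.data.frame(pt))
      expect_identical(featureNames(back), featureNames(pt))
      unlink(f)
    }
  }
})

test_that("pose table schema and integrity violations are rejected", {
  df <- tinyPoseDf()
  dup <- rbind(df, df[1, ])
  expect_error(PoseTable(dup), "duplicate")
  f <- tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "ligand_id")], f, row.names = FALSE)
  expect_error(readPoseTable(f), "missing key column")
  bad <- df
  bad$vdw_ext <- as.character(bad$vdw_ext)
  bad$vdw_ext[2] <- "oops"
  write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(readPoseTable(f), "non-numeric feature.*vdw_ext")
  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(readPoseTable(f), "duplicate key")
  unlink(f)
})

test_that("descriptor and affinity tables round-trip, with empty-field NA", {
  set.seed(3)
  m <- matrix(rnorm(30), 6, 5,
              dimnames = list(sprintf("L%d", 1:6), sprintf("d%d", 1:5)))
  m[2, 3] <- NA
  dt <- DescriptorTable(m)
  f <- tempfile(fileext = ".csv")
  writeDescriptorTable(dt, f)
  expect_equal(descriptorMatrix(readDescriptorTable(f)), m)

  at <- AffinityTable(sprintf("L%d", 1:6), rnorm(6, 6),
                      boundFlag = c(TRUE, rep(FALSE, 5)))
  writeAffinityTable(at, f)
  back <- readAffinityTable(f, kiUnits = "pKi")
  expect_equal(pKi(back), pKi(at))
  expect_equal(boundFlag(back), boundFlag(at))
  unlink(f)
})

test_that("Ki unit conversion follows the pKi definition", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(ligand_id = c("a", "b"), ki = c(1e-9, 1e-6)), f,
            row.names = FALSE)
  expect_equal(unname(pKi(readAffinityTable(f, "M"))), c(9, 6))
  write.csv(data.frame(ligand_id = c("a", "b"), ki = c(10, 1)), f,
            row.names = FALSE)
  expect_equal(unname(pKi(readAffinityTable(f, "nM"))), c(8, 9))
  write.csv(data.frame(ligand_id = "a", ki = -1), f, row.names = FALSE)
  expect_error(readAffinityTable(f, "nM"), "positive")
  unlink(f)
})

test_that("pose RMSD matches the fixed-frame definition", {
  a <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(computePoseRmsd(a, a), 0)
  expect_equal(computePoseRmsd(a, matrix(c(3, 4, 0), 1, 3)), 5)
  A <- rbind(c(0, 0, 0), c(2, 0, 0))
  B <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(computePoseRmsd(A, B), sqrt(2))
  expect_error(computePoseRmsd(A, B[1, , drop = FALSE]), "equal-size")
  expect_error(computePoseRmsd(A[0, ], B[0, ]), "empty")
})

test_that("pose RMSD is symmetric, non-negative and translation-invariant", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    A <- matrix(rnorm(n * 3), n, 3)
    B <- matrix(rnorm(n * 3), n, 3)
    r <- computePoseRmsd(A, B)
    expect_gte(r, 0)
    expect_equal(computePoseRmsd(B, A), r)
    shift <- matrix(rnorm(3), n, 3, byrow = TRUE)
    expect_equal(computePoseRmsd(A + shift, B + shift), r)
    expect_equal(computePoseRmsd(A, A), 0)
  }
})

test_that("SDF coordinates feed the RMSD computation", {
  skip_if_not_installed("ChemmineR")
  # two conformations of a 3-heavy-atom fragment, second translated by 1 A
  # along x on one atom
  sdf <- c(
    "mol1", "  synthetic", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  1  4  1  0",
    "M  END", "$$$$",
    "mol2", "  synthetic", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.1000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  1  4  1  0",
    "M  END", "$$$$")
  f <- tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  coords <- readSdfCoords(f)
  expect_length(coords, 2)
  expect_equal(nrow(coords[[1]]), 3)  # hydrogens dropped
  expect_equal(computePoseRmsd(coords[[1]], coords[[2]]), sqrt(1 / 3))
  all4 <- readSdfCoords(f, heavyOnly = FALSE)
  expect_equal(nrow(all4[[1]]), 4)
  unlink(f)
})

test_that("model artifacts round-trip bit-for-bit and check version/kind", {
  fx <- linearFixture(n = 30, p = 4, noise = 0.1)
  art <- trainPoseModel("S1", local({
    df <- tinyPoseDf(nLigands = 5, nStructures = 1, nPoses = 3, seed = 2)
    df$observed_rmsd <- runif(nrow(df), 0, 4)
    PoseTable(df)
  }), grid = defaultSvrGrid(C = 4, gamma = 0.25, epsilon = 0.1, modes = "eps"),
  folds = 5, seed = 1)
  f <- tempfile(fileext = ".json")
  saveModel(art, f)
  back <- loadModel(f)
  set.seed(9)
  X <- matrix(rnorm(100 * 2), 100, 2)
  colnames(X) <- art@featureNames
  expect_identical(predictSvr(art, X), predictSvr(back, X))

  expect_error(loadModel(f, expectKind = "score"), "kind mismatch")
  doc <- jsonlite::read_json(f)
  doc$version <- "dockrescore-svr/99"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(loadModel(f), "incompatible")
  unlink(f)
})
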