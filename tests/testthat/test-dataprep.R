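test_that("descriptor cleaning drops missing and non-discriminating columns", {
  m <- cbind(good = c(1, 2, 3, 4), hasNA = c(1, NA, 3, 4),
             constant = rep(2, 4), nearConstant = c(1, 1, 1, 1 + 1e-12))
  rownames(m) <- paste0("L", 1:4)
  out <- descriptorMatrix(cleanDescriptors(DescriptorTable(m)))
  expect_identical(colnames(out), "good")

  full <- DescriptorTable(matrix(rnorm(20), 4, 5,
                                 dimnames = list(paste0("L", 1:4), paste0("d", 1:5))))
  expect_equal(descriptorMatrix(cleanDescriptors(full)),
               descriptorMatrix(full))
  allBad <- DescriptorTable(matrix(1, 4, 2,
                                   dimnames = list(paste0("L", 1:4), c("a", "b"))))
  expect_error(cleanDescriptors(allBad), "every descriptor")
})

test_that("intercorrelation filter removes exactly the redundant columns", {
  set.seed(21)
  x1 <- rnorm(30)
  m <- cbind(c1 = x1, c2 = 2 * x1, c3 = rnorm(30))
  rownames(m) <- paste0("L", 1:30)
  out <- colnames(descriptorMatrix(filterIntercorrelated(DescriptorTable(m))))
  expect_true("c3" %in% out)
  expect_length(intersect(out, c("c1", "c2")), 1L)

  # already-decorrelated table untouched
  ind <- DescriptorTable(matrix(rnorm(300), 30, 10,
                                dimnames = list(paste0("L", 1:30), paste0("d", 1:10))))
  expect_equal(dim(filterIntercorrelated(ind, 0.64))[2], 10)

  # threshold 0: any pair correlates with r2 >= 0, so one column survives
  expect_equal(dim(filterIntercorrelated(ind, 0))[2], 1)

  # target-guided drop rule keeps the more response-relevant column
  m2 <- m
  m2[, "c2"] <- 2 * x1 + rnorm(30, sd = 0.2)  # still r2 >= 0.64 with c1
  y <- m2[, "c2"] + rnorm(30, sd = 1e-3)
  expect_gte(cor(m2[, "c1"], m2[, "c2"])^2, 0.64)
  kept <- colnames(descriptorMatrix(
    filterIntercorrelated(DescriptorTable(m2), target = y)))
  expect_true("c2" %in% kept)
  expect_false("c1" %in% kept)
})

test_that("no surviving pair exceeds the intercorrelation threshold (property)", {
  set.seed(22)
  for (i in 1:10) {
    p <- sample(5:25, 1)
    base <- matrix(rnorm(20 * p), 20, p)
    # inject correlated clones
    for (j in seq_len(p %/% 3))
      base[, j] <- base[, p + 1 - j] * 0.95 + rnorm(20, sd = 0.1)
    colnames(base) <- paste0("d", seq_len(p))
    rownames(base) <- paste0("L", 1:20)
    thr <- sample(c(0.3, 0.5, 0.64, 0.8), 1)
    out <- descriptorMatrix(filterIntercorrelated(DescriptorTable(base), thr))
    if (ncol(out) >= 2) {
      r2 <- cor(out)^2
      diag(r2) <- 0
      expect_lt(max(r2), thr)
    }
  }
})

test_that("normalizer centers and scales on training rows only", {
  m <- matrix(c(1, 2, 3, 10), 4, 1, dimnames = list(paste0("L", 1:4), "d1"))
  stats <- fitNormalizer(DescriptorTable(m), trainIds = paste0("L", 1:3))
  z <- descriptorMatrix(applyNormalizer(stats, DescriptorTable(m)))
  expect_equal(unname(z[1:3, 1]), c(-1, 0, 1))   # sample sd of 1,2,3 is 1
  expect_equal(unname(z[4, 1]), 8)               # held-out row uses train stats
  # held-out row equal to the training mean maps to zero
  expect_equal(unname(descriptorMatrix(applyNormalizer(
    stats, DescriptorTable(matrix(2, 1, 1, dimnames = list("Lx", "d1")))))[1, 1]), 0)

  set.seed(4)
  big <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("L", 1:20), paste0("d", 1:10)))
  st <- fitNormalizer(big)
  back <- invertNormalizer(st, applyNormalizer(st, big))
  expect_lt(max(abs(back - big)), 1e-12)

  const <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
                  dimnames = list(paste0("L", 1:3), c("a", "b")))
  expect_error(fitNormalizer(const), "zero-variance.*clean")
})

test_that("normalization statistics never depend on test rows", {
  set.seed(14)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(paste0("L", 1:12), paste0("d", 1:5)))
  tr <- paste0("L", 1:8)
  s1 <- fitNormalizer(DescriptorTable(m), tr)
  m2 <- m
  m2[9:12, ] <- m2[9:12, ] + 100  # perturb held-out rows only
  s2 <- fitNormalizer(DescriptorTable(m2), tr)
  expect_identical(s1$center, s2$center)
  expect_identical(s1$scale, s2$scale)
})

test_that("Kennard-Stone reproduces hand-computed and preset splits", {
  # 37 samples at 2:1 -> 24 train / 13 test
  set.seed(8)
  X <- matrix(rnorm(37 * 4), 37, 4, dimnames = list(sprintf("m%02d", 1:37), NULL))
  sp <- kennardStoneSplit(X, ratio = 2)
  expect_length(sp$trainIds, 24)
  expect_length(sp$testIds, 13)
  expect_setequal(c(sp$trainIds, sp$testIds), rownames(X))

  # 1-D hand case: points 0..4, train size 3 -> {0, 4, 2}
  X1 <- matrix(0:4, 5, 1, dimnames = list(letters[1:5], NULL))
  sp1 <- kennardStoneSplit(X1, trainSize = 3)
  expect_identical(sp1$trainIds, c("a", "e", "c"))
  expect_identical(sp1$testIds, c("b", "d"))

  # 2 rows at 1:1: train holds the lower-index member of the max pair
  X2 <- matrix(c(0, 1), 2, 1, dimnames = list(c("p", "q"), NULL))
  sp2 <- kennardStoneSplit(X2, ratio = 1)
  expect_identical(sp2$trainIds, "p")
  expect_error(kennardStoneSplit(X2[1, , drop = FALSE]), "at least 2")
})

test_that("Kennard-Stone invariants hold on random instances", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    X <- matrix(rnorm(n * sample(1:5, 1)), n)
    rownames(X) <- sprintf("r%03d", seq_len(n))
    sp <- kennardStoneSplit(X, ratio = 2)
    expect_length(intersect(sp$trainIds, sp$testIds), 0)
    expect_setequal(c(sp$trainIds, sp$testIds), rownames(X))
    expect_length(sp$trainIds, floor(2 * n / 3))
    D <- as.matrix(dist(X))
    expect_equal(D[sp$trainIds[1], sp$trainIds[2]], max(D))
    # deterministic
    expect_identical(kennardStoneSplit(X, ratio = 2)$trainIds, sp$trainIds)
  }
})

test_that("split diagnostics summarize coverage and principal components", {
  set.seed(16)
  m <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("L%02d", 1:40), paste0("d", 1:6)))
  aff <- AffinityTable(rownames(m), rnorm(40, 6))
  sp <- kennardStoneSplit(m, 2)
  d <- splitDiagnostics(DescriptorTable(m), aff, sp)
  expect_named(d, c("pkiSummary", "pkiHist", "descriptorMeans", "pcVariance"))
  expect_equal(sum(d$pkiHist$train) + sum(d$pkiHist$test), 40)
  # isotropic cloud: leading PCs explain roughly equal variance
  expect_lt(max(d$pcVariance) / min(d$pcVariance), 3)

  one <- matrix(rnorm(40), 40, 1, dimnames = list(rownames(m), "d1"))
  d1 <- splitDiagnostics(DescriptorTable(one), aff, sp, nPc = 1)
  expect_equal(unname(d1$pcVariance), 1)  # single feature: PC1 = 100%
})
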