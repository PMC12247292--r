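test_that("scoring matches a cell-by-cell counting oracle and conserves mass", {
  truth <- matrix(c(1L, 2L), 2, 4)
  expect_equal(scoreCalls(truth, truth),
               data.frame(pct_correct = 100, pct_incorrect = 0,
                          pct_unassigned = 0, yield = 1, accuracy = 1))
  allM <- matrix(0L, 2, 4)
  sM <- scoreCalls(allM, truth)
  expect_equal(sM$pct_unassigned, 100)
  expect_true(is.na(sM$accuracy))

  set.seed(2)
  for (i in 1:5) {
    truth <- matrix(sample(c(1L, 2L), 100, replace = TRUE), 10, 10)
    calls <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    s <- scoreCalls(calls, truth)
    # brute-force cell count
    nc <- 0L; ni <- 0L; nu <- 0L
    for (a in 1:10) for (b in 1:10) {
      if (calls[a, b] == 0L) nu <- nu + 1L
      else if (calls[a, b] == truth[a, b]) nc <- nc + 1L
      else ni <- ni + 1L
    }
    expect_equal(s$pct_correct, nc)
    expect_equal(s$pct_incorrect, ni)
    expect_equal(s$pct_unassigned, nu)
    expect_equal(s$pct_correct + s$pct_incorrect + s$pct_unassigned, 100)
    expect_equal(s$yield, (nc + ni) / 100)
    expect_equal(s$accuracy, nc / (nc + ni))
  }
  expect_error(scoreCalls(matrix(0L, 2, 3), matrix(1L, 2, 4)), "aligned")
})

test_that("FST limit cases are exact", {
  A <- matrix(0L, 10, 5); B <- matrix(1L, 10, 5)
  expect_equal(fstGlobal(A, B), 1)
  expect_equal(fstGlobal(A, B, estimator = "wc"), 1)
  set.seed(4)
  X <- randomHaps(40, 50)
  expect_lt(abs(fstGlobal(X, X)), 0.05) # identical groups: no differentiation
  expect_error(fstGlobal(A, A), "monomorphic")
  expect_error(fstGlobal(A[1, , drop = FALSE], B), "at least 2")
})

test_that("FST with preset frequencies equals the hand formula", {
  nl <- 50L
  # exact frequencies 0.2 vs 0.8 in 40 haplotypes (20 diploid individuals)
  A <- matrix(rep(c(rep(1L, 8), rep(0L, 32)), nl), 40, nl)
  B <- matrix(rep(c(rep(1L, 32), rep(0L, 8)), nl), 40, nl)
  p1 <- 0.2; p2 <- 0.8; n1 <- 40; n2 <- 40
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(fstGlobal(A, B), num / den)
  # the two estimators agree on this symmetric case to first order
  expect_lt(abs(fstGlobal(A, B, "wc") - num / den), 0.05)
})

test_that("PCA separates duplicated-row clusters and matches prcomp", {
  base1 <- rbinom(30, 2, 0.2)
  base2 <- rbinom(30, 2, 0.8)
  X <- rbind(matrix(base1, 5, 30, byrow = TRUE),
             matrix(base2, 5, 30, byrow = TRUE))
  sc <- pcaGenotypes(X, nComp = 2)
  expect_lt(max(abs(diff(sc[1:5, 1]))), 1e-8)  # no within-cluster spread
  expect_lt(max(abs(diff(sc[6:10, 1]))), 1e-8)
  expect_gt(abs(mean(sc[1:5, 1]) - mean(sc[6:10, 1])), 1)

  set.seed(13)
  Y <- matrix(rbinom(100, 2, 0.5), 10, 10)
  scY <- pcaGenotypes(Y, nComp = 3)
  pr <- prcomp(Y, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    expect_lt(min(max(abs(scY[, k] - pr$x[, k])),
                  max(abs(scY[, k] + pr$x[, k]))), 1e-8) # up to sign
  }
  # locus reordering leaves coordinates unchanged up to sign
  perm <- sample(10)
  scP <- pcaGenotypes(Y[, perm], nComp = 2)
  for (k in 1:2) {
    expect_lt(min(max(abs(scY[, k] - scP[, k])),
                  max(abs(scY[, k] + scP[, k]))), 1e-8)
  }
  expect_error(pcaGenotypes(Y[1:2, ]), "at least 3")
  expect_error(pcaGenotypes(matrix(1, 5, 4)), "zero variance")
})

test_that("call counting matches manual tallies", {
  calls <- rbind(c(1L, 1L, 0L, 2L), c(2L, 2L, 2L, 0L))
  cc <- countCalls(calls)
  expect_equal(cc$n_local, mean(c(2, 0)))
  expect_equal(cc$n_exotic, mean(c(1, 3)))
  expect_equal(cc$n_unassigned, mean(c(1, 1)))
  expect_equal(cc$yield, 6 / 8)
})

test_that("first-generation crossbreds sit between the founder breeds on PC1", {
  fs <- simulateFounders(smallFounderConfig(), seed = 9)
  prog <- runBreedingProgram(fs, breedingConfig(gensLocalMating = 2,
                                                nDams = 60, nBulls = 10,
                                                nRounds = 1, nQtl = 20),
                             seed = 10)
  cb <- prog$crossbred[[1]]
  dosE <- dosageMatrix(cb$exoticPanel)
  dosL <- dosageMatrix(cb$localPanel)
  dosX <- dosageMatrix(cb$haplos)
  sc <- pcaGenotypes(rbind(dosE, dosL, dosX), nComp = 1)
  nE <- nrow(dosE); nL <- nrow(dosL)
  mE <- mean(sc[seq_len(nE), 1])
  mL <- mean(sc[nE + seq_len(nL), 1])
  mX <- mean(sc[(nE + nL + 1):nrow(sc), 1])
  expect_true((mX > min(mE, mL)) && (mX < max(mE, mL)))
})
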