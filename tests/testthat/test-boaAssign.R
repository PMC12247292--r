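test_that("haplotype libraries deduplicate with correct counts", {
  H <- matrix(rep(c(0L, 1L, 0L, 1L), 10), 10, 4, byrow = TRUE)
  hs <- makeHaploSet(H)
  lib <- buildLibrary(hs, 0, 4, "EXOTIC")
  expect_equal(nrow(libraryEntries(lib)), 1L)
  expect_equal(libraryCounts(lib), 10L)

  Hd <- diag(1L, 8, 8) # pairwise distinct rows
  libD <- buildLibrary(makeHaploSet(Hd), 0, 8)
  expect_equal(nrow(libraryEntries(libD)), 8L)
  expect_equal(sum(libraryCounts(libD)), 8L)
})

test_that("library construction equals a pairwise-comparison oracle", {
  set.seed(9)
  H <- randomHaps(20, 6, p = 0.3)
  lib <- buildLibrary(makeHaploSet(H), 1, 5)
  W <- H[, 2:5, drop = FALSE]
  # hash-free oracle: first-occurrence scan with row-by-row comparisons
  uniq <- list(); cnt <- integer()
  for (i in seq_len(nrow(W))) {
    hit <- 0L
    for (j in seq_along(uniq)) {
      if (all(uniq[[j]] == W[i, ])) { hit <- j; break }
    }
    if (hit == 0L) { uniq[[length(uniq) + 1L]] <- W[i, ]; cnt <- c(cnt, 1L) }
    else cnt[hit] <- cnt[hit] + 1L
  }
  expect_equal(nrow(libraryEntries(lib)), length(uniq))
  expect_equal(libraryCounts(lib), cnt)
  for (j in seq_along(uniq)) {
    expect_equal(libraryEntries(lib)[j, ], uniq[[j]])
  }
})

test_that("mismatches is the Hamming distance", {
  expect_equal(mismatches(c(0L, 1L, 1L), c(0L, 1L, 1L)), 0L)
  expect_equal(mismatches(rep(0L, 10), rep(1L, 10)), 10L)
  expect_error(mismatches(c(0L, 1L), c(0L, 1L, 0L)), "length")
  set.seed(3)
  a <- rbinom(40, 1, 0.5); b <- rbinom(40, 1, 0.5)
  loop <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) loop <- loop + 1L
  expect_equal(mismatches(a, b), loop)
})

test_that("bestMatch equals an exhaustive scan oracle", {
  set.seed(17)
  H <- randomHaps(16, 10)
  lib <- buildLibrary(makeHaploSet(H), 0, 10)
  # a library member matches itself
  r <- bestMatch(H[4, ], lib)
  expect_equal(r$min, 0L)
  expect_gte(r$nmin, 1L)
  # the stated toy: all-zeros library vs all-ones target
  lib0 <- buildLibrary(makeHaploSet(matrix(0L, 4, 10)), 0, 10)
  expect_equal(bestMatch(rep(1L, 10), lib0), list(min = 10L, nmin = 1L))
  # random target vs full enumeration
  for (i in 1:5) {
    tgt <- rbinom(10, 1, 0.5)
    d <- apply(libraryEntries(lib), 1, function(e) sum(e != tgt))
    r <- bestMatch(tgt, lib)
    expect_equal(r$min, min(d))
    expect_equal(r$nmin, sum(d == min(d)))
  }
})

test_that("core assignment follows the fewest-mismatch rule with ties missing", {
  codes <- boaCodes()
  target <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L)
  # local library contains the target exactly; exotic's best entry has >= 1 mismatch
  libL <- buildLibrary(makeHaploSet(rbind(target, target, 1L - target,
                                          1L - target)), 0, 10, "LOCAL")
  flip1 <- target; flip1[3] <- 1L - flip1[3]
  libE <- buildLibrary(makeHaploSet(rbind(flip1, 1L - target)), 0, 10, "EXOTIC")
  expect_equal(assignCore(target, libE, libL), unname(codes["LOCAL"]))
  # equally good matches in both libraries give a missing call
  libE2 <- buildLibrary(makeHaploSet(rbind(target, target)), 0, 10, "EXOTIC")
  expect_equal(assignCore(target, libE2, libL), unname(codes["MISSING"]))
  # mismatched cores are rejected
  libBad <- buildLibrary(makeHaploSet(rbind(target, target)), 0, 9, "EXOTIC")
  expect_error(assignCore(target[1:9], libBad, libL), "different cores")
})

test_that("the minimum match fraction can veto a winning library", {
  codes <- boaCodes()
  target <- rep(c(1L, 0L), 5)
  e1 <- target; e1[1] <- 1L - e1[1]               # 1 mismatch -> match 0.9
  l1 <- target; l1[1:3] <- 1L - l1[1:3]           # 3 mismatches
  libE <- buildLibrary(makeHaploSet(rbind(e1, e1)), 0, 10, "EXOTIC")
  libL <- buildLibrary(makeHaploSet(rbind(l1, l1)), 0, 10, "LOCAL")
  expect_equal(assignCore(target, libE, libL, minMatchFraction = 0.95),
               unname(codes["MISSING"]))
  expect_equal(assignCore(target, libE, libL),
               unname(codes["EXOTIC"]))
})

test_that("assignAll gives exotic everywhere for a haplotype copied from the exotic panel", {
  set.seed(23)
  nl <- 40L
  E <- randomHaps(12, nl, p = 0.8)
  L <- randomHaps(12, nl, p = 0.2)
  cross <- makeHaploSet(E[1:2, , drop = FALSE]) # verbatim exotic haplotypes
  asg <- assignAll(cross, makeHaploSet(E), makeHaploSet(L),
                   phasingScheme(c(10L, 20L)))
  for (s in seq_len(nrow(asg@scenarios))) {
    expect_true(all(expandCalls(asg, s) == boaCodes()["EXOTIC"]))
  }
})

test_that("identical panels make every call missing", {
  set.seed(8)
  P <- randomHaps(10, 30)
  cross <- makeHaploSet(randomHaps(6, 30))
  asg <- assignAll(cross, makeHaploSet(P), makeHaploSet(P),
                   phasingScheme(c(10L, 15L)))
  for (s in seq_len(nrow(asg@scenarios))) {
    expect_true(all(expandCalls(asg, s) == boaCodes()["MISSING"]))
  }
})

test_that("assignAll equals the per-core oracle on small random instances", {
  sch <- phasingScheme(c(7L, 13L))
  for (seed in 1:3) {
    set.seed(seed)
    nl <- 40L
    cross <- makeHaploSet(randomHaps(20, nl, p = 0.5))
    ep <- makeHaploSet(randomHaps(30, nl, p = 0.7))
    lp <- makeHaploSet(randomHaps(30, nl, p = 0.3))
    asg <- assignAll(cross, ep, lp, sch)
    oracle <- oracleAssignAll(cross, ep, lp, sch)
    for (s in seq_along(oracle)) {
      expect_identical(unname(asg@calls[[s]]), unname(oracle[[s]]))
    }
    # with a match-fraction threshold as well
    asgT <- assignAll(cross, ep, lp, sch, minMatchFraction = 0.8)
    oracleT <- oracleAssignAll(cross, ep, lp, sch, minMatchFraction = 0.8)
    for (s in seq_along(oracleT)) {
      expect_identical(unname(asgT@calls[[s]]), unname(oracleT[[s]]))
    }
  }
})

test_that("swapping the two panels swaps exotic and local calls and fixes missing", {
  set.seed(14)
  nl <- 30L
  cross <- makeHaploSet(randomHaps(10, nl))
  ep <- makeHaploSet(randomHaps(16, nl, p = 0.7))
  lp <- makeHaploSet(randomHaps(16, nl, p = 0.3))
  sch <- phasingScheme(c(10L, 15L))
  a1 <- assignAll(cross, ep, lp, sch)
  a2 <- assignAll(cross, lp, ep, sch)
  codes <- boaCodes()
  for (s in seq_along(a1@calls)) {
    c1 <- a1@calls[[s]]; c2 <- a2@calls[[s]]
    expect_identical(c1 == codes["MISSING"], c2 == codes["MISSING"])
    expect_identical(c1 == codes["EXOTIC"], c2 == codes["LOCAL"])
    expect_identical(c1 == codes["LOCAL"], c2 == codes["EXOTIC"])
  }
})

test_that("adding the target to a library can only improve its best match", {
  set.seed(6)
  for (i in 1:10) {
    H <- randomHaps(12, 15)
    tgt <- rbinom(15, 1, 0.5)
    lib <- buildLibrary(makeHaploSet(H), 0, 15)
    libPlus <- buildLibrary(makeHaploSet(rbind(H, tgt, tgt, deparse.level = 0)),
                            0, 15)
    expect_lte(bestMatch(tgt, libPlus)$min, bestMatch(tgt, lib)$min)
    expect_equal(bestMatch(tgt, libPlus)$min, 0L)
  }
})

test_that("panels with a different locus set are rejected", {
  cross <- makeHaploSet(randomHaps(4, 20))
  ep <- makeHaploSet(randomHaps(4, 19))
  lp <- makeHaploSet(randomHaps(4, 20))
  expect_error(assignAll(cross, ep, lp, phasingScheme(10L)), "locus set")
})
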