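codesT <- boaCodes()

test_that("consensus of one allele follows the agreement rule", {
  L <- unname(codesT["LOCAL"]); E <- unname(codesT["EXOTIC"])
  M <- unname(codesT["MISSING"])
  # unanimity survives any threshold
  for (tau in thresholdGrid()) {
    expect_equal(consensusAllele(rep(L, 20), tau), L)
  }
  # an exact tie is always missing
  expect_equal(consensusAllele(c(rep(L, 10), rep(E, 10)), 0.5), M)
  # 12 local vs 8 exotic: agreement 0.6
  votes <- c(rep(L, 12), rep(E, 8))
  expect_equal(consensusAllele(votes, 0.50), L)
  expect_equal(consensusAllele(votes, 0.65), M)
  # all votes missing
  expect_equal(consensusAllele(rep(M, 20), 0.5), M)
  expect_error(consensusAllele(integer(0), 0.5), "empty")
  # missing votes do not count against the leader by default ...
  votes2 <- c(rep(L, 9), rep(M, 11))
  expect_equal(consensusAllele(votes2, 0.9), L)
  # ... but do when the all-votes denominator is requested
  expect_equal(consensusAllele(votes2, 0.9, allVotesDenominator = TRUE), M)
})

test_that("consensus matrices equal the looped per-allele oracle", {
  set.seed(10)
  nl <- 24L
  cross <- makeHaploSet(randomHaps(8, nl))
  ep <- makeHaploSet(randomHaps(10, nl, p = 0.75))
  lp <- makeHaploSet(randomHaps(10, nl, p = 0.25))
  asg <- assignAll(cross, ep, lp, phasingScheme(c(6L, 9L, 12L)))
  cons <- consensusCalls(asg)
  perLocus <- lapply(seq_len(nrow(asg@scenarios)),
                     function(s) expandCalls(asg, s))
  for (tau in c(0.5, 0.7, 0.95)) {
    cm <- consensusAt(cons, tau)
    for (h in seq_len(nrow(cm))) {
      for (j in seq_len(nl)) {
        votes <- vapply(perLocus, function(m) m[h, j], integer(1))
        expect_identical(cm[h, j], consensusAllele(votes, tau))
      }
    }
  }
})

test_that("an assignment where every scenario agrees passes through unchanged", {
  set.seed(44)
  nl <- 30L
  E <- randomHaps(10, nl, p = 0.9)
  L <- randomHaps(10, nl, p = 0.1)
  cross <- makeHaploSet(rbind(E[1:2, ], L[1:2, ]))
  asg <- assignAll(cross, makeHaploSet(E), makeHaploSet(L),
                   phasingScheme(c(10L, 15L)))
  agree <- all(vapply(seq_len(nrow(asg@scenarios)), function(s) {
    all(expandCalls(asg, s) == expandCalls(asg, 1L))
  }, logical(1)))
  if (agree) {
    cons <- consensusCalls(asg)
    for (tau in thresholdGrid()) {
      expect_identical(consensusAt(cons, tau), expandCalls(asg, 1L))
    }
  }
})

test_that("consensus is exactly monotone in the threshold and invents no labels", {
  set.seed(12)
  for (rep in 1:3) {
    nl <- 30L
    cross <- makeHaploSet(randomHaps(10, nl))
    ep <- makeHaploSet(randomHaps(12, nl, p = 0.7))
    lp <- makeHaploSet(randomHaps(12, nl, p = 0.3))
    asg <- assignAll(cross, ep, lp, phasingScheme(c(6L, 10L, 15L)))
    cons <- consensusCalls(asg)
    taus <- cons@thresholds
    votesAny <- Reduce(`|`, lapply(seq_len(nrow(asg@scenarios)), function(s) {
      expandCalls(asg, s) != codesT["MISSING"]
    }))
    for (k in seq_along(taus)[-1]) {
      lo <- consensusAt(cons, taus[k - 1])
      hi <- consensusAt(cons, taus[k])
      assignedHi <- hi != codesT["MISSING"]
      # anything assigned at the stricter threshold is identical at the looser
      expect_true(all(lo[assignedHi] == hi[assignedHi]))
      # yield is non-increasing, exactly
      expect_gte(sum(lo != codesT["MISSING"]), sum(assignedHi))
    }
    # no call appears where no scenario voted a breed
    c50 <- consensusAt(cons, 0.5)
    expect_true(all(c50[!votesAny] == codesT["MISSING"]))
  }
})

test_that("the fused experiment scorer matches the public consensus pipeline", {
  set.seed(21)
  nl <- 36L
  cross <- makeHaploSet(randomHaps(10, nl))
  ep <- makeHaploSet(randomHaps(14, nl, p = 0.8))
  lp <- makeHaploSet(randomHaps(14, nl, p = 0.2))
  truth <- matrix(sample(c(1L, 2L), 10 * nl, replace = TRUE), 10, nl)
  asg <- assignAll(cross, ep, lp, phasingScheme(c(9L, 12L)))
  ev <- crossBOA:::.evaluateCohort(asg, truth, thresholdGrid(), FALSE)
  slow <- scoreConsensus(consensusCalls(asg), truth)
  expect_equal(ev$consensus, slow)
  expect_equal(ev$core[, -(1:2)], scoreAssignments(asg, truth)[, -(1:2)])
})
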