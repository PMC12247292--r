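test_that("a zero-length map copies one parental chromosome intact", {
  hp <- rbind(rep(0L, 20), rep(1L, 20))
  op <- rbind(rep(5L, 20), rep(6L, 20))
  for (s in 1:10) {
    g <- meiosis(hp, seq(0, 0, length.out = 20), mapLength = 0,
                 originpair = op, seed = s)
    expect_true(all(g$haplotype == 0L) || all(g$haplotype == 1L))
    expect_equal(unique(g$origin), if (g$haplotype[1] == 0L) 5L else 6L)
  }
})

test_that("origin rows are cut at exactly the haplotype breakpoints", {
  nl <- 200L
  hp <- rbind(rep(0L, nl), rep(1L, nl))
  op <- rbind(rep(2L, nl), rep(1L, nl)) # all-exotic / all-local parent
  pos <- seq(0.001, 0.999, length.out = nl)
  for (s in 1:25) {
    g <- meiosis(hp, pos, mapLength = 1, originpair = op, seed = s)
    # the haplotype reveals the chromatid at every locus; origin must track it
    expect_equal(g$origin, ifelse(g$haplotype == 0L, 2L, 1L))
  }
})

test_that("crossover count is Poisson with mean equal to the map length", {
  nl <- 100L
  hp <- rbind(rep(0L, nl), rep(1L, nl))
  pos <- seq(0.0005, 0.9995, length.out = nl)
  set.seed(202)
  n <- 1e4
  xo <- vapply(seq_len(n), function(i) {
    g <- meiosis(hp, pos, mapLength = 1)
    sum(diff(g$haplotype) != 0L)
  }, numeric(1))
  # mean within 3 SE of the 1-Morgan expectation
  expect_lt(abs(mean(xo) - 1), 3 * sd(xo) / sqrt(n))
  expect_gte(mean(xo), 0.97)
  expect_lte(mean(xo), 1.03)
})

test_that("every origin cell of an offspring comes from its parent at that locus", {
  set.seed(31)
  nl <- 50L
  H <- randomHaps(4, nl)
  O <- matrix(sample(3:8, 4 * nl, replace = TRUE), 4, nl) # distinct codes
  pos <- seq(0.01, 0.99, length.out = nl)
  res <- cpp_next_gen_traced(H, O, pos, dams = rep(0L, 20), sires = rep(1L, 20),
                             mapLen = 1)
  for (r in seq_len(nrow(res$origins))) {
    p <- if (r %% 2L == 1L) 0L else 1L # maternal rows from dam 0, paternal from sire 1
    fromP1 <- res$origins[r, ] == O[2L * p + 1L, ]
    fromP2 <- res$origins[r, ] == O[2L * p + 2L, ]
    expect_true(all(fromP1 | fromP2))
    # and the haplotype came from the same chromatid as the origin
    hapOk <- (fromP1 & res$haplotypes[r, ] == H[2L * p + 1L, ]) |
             (fromP2 & res$haplotypes[r, ] == H[2L * p + 2L, ])
    expect_true(all(hapOk))
  }
})

test_that("the breeding program yields the specified cohort structure", {
  fs <- simulateFounders(tinyFounderConfig(), seed = 2)
  cfg <- tinyBreedingConfig()
  prog <- runBreedingProgram(fs, cfg, seed = 3)
  expect_length(prog$crossbred, cfg$nRounds)
  for (r in seq_len(cfg$nRounds)) {
    cb <- prog$crossbred[[r]]
    info <- sampleInfo(cb$haplos)
    expect_equal(nrow(info), cfg$calvingsPerDam * cfg$nDams)
    expect_equal(sum(info$sex == "F"), sum(info$sex == "M"))
    expect_identical(dim(cb$origins), dim(haploMatrix(cb$haplos)))
  }
  # F1 cohort: maternal haplotype all-local, paternal all-exotic
  o1 <- prog$crossbred[[1]]$origins
  mat <- o1[seq(1, nrow(o1), 2), ]
  pat <- o1[seq(2, nrow(o1), 2), ]
  expect_true(all(mat == boaCodes()["LOCAL"]))
  expect_true(all(pat == boaCodes()["EXOTIC"]))
})

test_that("true exotic dosage follows the backcross expectation 1 - 2^-g", {
  fs <- simulateFounders(smallFounderConfig(), seed = 4)
  cfg <- breedingConfig(gensLocalMating = 3, nDams = 100, nBulls = 10,
                        nRounds = 4, nQtl = 20)
  prog <- runBreedingProgram(fs, cfg, seed = 5)
  for (r in seq_len(cfg$nRounds)) {
    dos <- trueExoticDosage(prog$crossbred[[r]]$origins)
    se <- sd(dos) / sqrt(length(dos))
    expect_lt(abs(mean(dos) - (1 - 2^-r)), 3 * se + 1e-12)
  }
})

test_that("the pedigree is closed and reproducible", {
  fs <- simulateFounders(tinyFounderConfig(), seed = 2)
  prog <- runBreedingProgram(fs, tinyBreedingConfig(), seed = 3)
  ped <- prog$pedigree
  nonf <- ped[!is.na(ped$sire), ]
  expect_true(all(nonf$sire %in% ped$id))
  expect_true(all(nonf$dam %in% ped$id))
  expect_false(anyDuplicated(ped$id) > 0)
  prog2 <- runBreedingProgram(fs, tinyBreedingConfig(), seed = 3)
  expect_identical(haploMatrix(prog$crossbred[[2]]$haplos),
                   haploMatrix(prog2$crossbred[[2]]$haplos))
  expect_identical(prog$crossbred[[2]]$origins, prog2$crossbred[[2]]$origins)
})

test_that("selection on the trait raises cohort mean genetic value over random choice", {
  fs <- simulateFounders(smallFounderConfig(), seed = 6)
  pop <- sampleInfo(fs)$population
  base <- subsetIndividuals(fs, pop != "EXOTIC")
  gain <- sapply(1:10, function(s) {
    arch <- sampleTraitArchitecture(base, nQtl = 50, seed = s)
    gv <- geneticValues(dosageMatrix(base), arch)
    phen <- simulatePhenotype(gv, arch$envVar, seed = s + 50)
    sex <- rep(c("F", "M"), length.out = length(gv))
    sel <- selectTopFemales(phen, sex, 50)
    set.seed(s)
    rnd <- sample(which(sex == "F"), 50)
    mean(gv[sel]) - mean(gv[rnd])
  })
  expect_gt(t.test(gain, alternative = "greater")$statistic, 2.33)
})

test_that("true exotic dosage equals a brute-force cell count", {
  set.seed(77)
  o <- matrix(sample(c(1L, 2L), 6 * 40, replace = TRUE), 6, 40)
  expect_equal(trueExoticDosage(o, by = "haplotype"),
               apply(o, 1, function(r) sum(r == 2L) / length(r)))
  byInd <- trueExoticDosage(o)
  for (i in 1:3) {
    cells <- o[c(2 * i - 1, 2 * i), ]
    expect_equal(byInd[i], sum(cells == 2L) / length(cells))
  }
  expect_equal(trueExoticDosage(matrix(2L, 2, 5)), 1)
})
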