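# Small fixture builders shared across the test files.

# HaploSet from a raw 0/1 matrix (two rows per individual)
makeHaploSet <- function(H, population = "TEST", generation = "TEST",
                         positions = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  n <- nrow(H) %/% 2L
  if (is.null(positions)) positions <- seq(0.01, 0.99, length.out = ncol(H))
  HaploSet(H, positions,
           data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                      population = rep_len(population, n),
                      generation = rep_len(generation, n),
                      stringsAsFactors = FALSE))
}

# random 0/1 haplotype matrix
randomHaps <- function(nHap, nLoci, p = 0.5) {
  matrix(rbinom(nHap * nLoci, 1L, p), nHap, nLoci)
}

# a founder configuration small enough for fast unit tests
tinyFounderConfig <- function(...) {
  args <- utils::modifyList(
    list(nLoci = 60L, popSize = 25L, ancestralNe = 50L, breedNe = 25L,
         burnIn = 5L, nCandidateLoci = 300L, splitDepthExotic = 6L,
         splitDepthLocal = 3L),
    list(...))
  do.call(founderConfig, args)
}

# a mid-sized configuration for statistical checks
smallFounderConfig <- function(...) {
  args <- utils::modifyList(
    list(nLoci = 200L, popSize = 100L, ancestralNe = 200L, breedNe = 50L,
         burnIn = 10L, nCandidateLoci = 600L, splitDepthExotic = 10L,
         splitDepthLocal = 5L),
    list(...))
  do.call(founderConfig, args)
}

tinyBreedingConfig <- function(...) {
  breedingConfig(gensLocalMating = 2, nDams = 20, nBulls = 5, nRounds = 2,
                 nQtl = 10, ...)
}

# R-level brute-force assignment oracle: loops mismatches()/bestMatch()/
# assignCore() over every core and haplotype, independently of the C++ path
oracleAssignAll <- function(crossbreds, exoticPanel, localPanel, scheme,
                            minMatchFraction = NULL) {
  H <- haploMatrix(crossbreds)
  nl <- nLoci(crossbreds)
  out <- list()
  scen <- scheme$scenarios
  for (s in seq_len(nrow(scen))) {
    cores <- makeCores(nl, scen$core_length[s], scen$offset[s])
    cmat <- matrix(0L, nrow(H), nrow(cores))
    for (ci in seq_len(nrow(cores))) {
      libE <- buildLibrary(exoticPanel, cores$start[ci], cores$stop[ci], "EXOTIC")
      libL <- buildLibrary(localPanel, cores$start[ci], cores$stop[ci], "LOCAL")
      idx <- (cores$start[ci] + 1L):cores$stop[ci]
      for (h in seq_len(nrow(H))) {
        cmat[h, ci] <- assignCore(H[h, idx], libE, libL, minMatchFraction)
      }
    }
    out[[s]] <- cmat
  }
  out
}
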