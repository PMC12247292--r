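#' Single meiosis with origin tracking
#'
#' Forms one gamete from a parent's haplotype pair under a no-interference
#' model: the crossover count is Poisson(map length in Morgans), breakpoint
#' positions are uniform on the map, and the starting chromatid is chosen at
#' random. The origin pair, when supplied, is cut at the same breakpoints as
#' the haplotypes, which is how the true founder breed of every allele is
#' carried through the pedigree.
#'
#' @param haplopair 2 x nLoci 0/1 matrix (the parent's haplotypes).
#' @param positions map positions in Morgans, one per locus.
#' @param mapLength map length in Morgans.
#' @param originpair optional 2 x nLoci integer matrix of origin codes.
#' @param seed optional integer seed.
#' @return A list with \code{haplotype} and (if \code{originpair} was given)
#'   \code{origin}, each a length-nLoci integer vector.
#' @examples
#' hp <- rbind(rep(0L, 10), rep(1L, 10))
#' op <- rbind(rep(2L, 10), rep(1L, 10))
#' g <- meiosis(hp, seq(0, 0.9, by = 0.1), mapLength = 1, originpair = op,
#'              seed = 1)
#' g$origin
#' @export
meiosis <- function(haplopair, positions, mapLength, originpair = NULL,
                    seed = NULL) {
  stopifnot(nrow(haplopair) == 2L, length(positions) == ncol(haplopair),
            mapLength >= 0)
  if (!is.null(seed)) set.seed(seed)
  op <- if (is.null(originpair)) haplopair else originpair
  stopifnot(nrow(op) == 2L, ncol(op) == ncol(haplopair))
  res <- cpp_gamete(as.integer(haplopair[1L, ]), as.integer(haplopair[2L, ]),
                    as.integer(op[1L, ]), as.integer(op[2L, ]),
                    as.numeric(positions), mapLength)
  if (is.null(originpair)) list(haplotype = res$haplotype)
  else list(haplotype = res$haplotype, origin = res$origin)
}

#' Configuration of the crossbreeding program
#'
#' Parameters of the simulated smallholder program: the pooled local breeds
#' are mated at random for \code{gensLocalMating} generations, the
#' \code{nDams} best cows are selected on a trait with heritability
#' \code{h2}, and for each of \code{nRounds} rounds the dams are mated to
#' \code{nBulls} newly drawn exotic sires, each dam calving
#' \code{calvingsPerDam} times with an enforced 1:1 sex ratio; all female
#' calves replace the dams for the next round. Exotic and local purebred
#' populations are propagated in parallel by random mating at constant size
#' and serve as the contemporaneous reference panels of each round.
#'
#' @param gensLocalMating random-mating generations among pooled local breeds
#'   before selection (default 10).
#' @param nDams number of cows selected and kept as dams (default 1000).
#' @param nBulls exotic bulls drawn (without replacement) per round
#'   (default 25).
#' @param nRounds crossbreeding rounds (default 5).
#' @param calvingsPerDam calvings per dam per round (default 2).
#' @param nQtl QTL underlying the selection trait (default 100).
#' @param h2 narrow-sense heritability of the trait (default 0.3).
#' @param deltaMean,deltaVar mean and variance of the dominance degree
#'   (defaults 0.1 and 0.1).
#' @param selectOn \code{"phenotype"} (default) or \code{"geneticValue"}:
#'   the criterion for the one selection event.
#' @return A list of class \code{"BreedingConfig"}.
#' @export
breedingConfig <- function(gensLocalMating = 10L, nDams = 1000L, nBulls = 25L,
                           nRounds = 5L, calvingsPerDam = 2L, nQtl = 100L,
                           h2 = 0.3, deltaMean = 0.1, deltaVar = 0.1,
                           selectOn = c("phenotype", "geneticValue")) {
  cfg <- list(
    gensLocalMating = as.integer(gensLocalMating), nDams = as.integer(nDams),
    nBulls = as.integer(nBulls), nRounds = as.integer(nRounds),
    calvingsPerDam = as.integer(calvingsPerDam), nQtl = as.integer(nQtl),
    h2 = as.numeric(h2), deltaMean = as.numeric(deltaMean),
    deltaVar = as.numeric(deltaVar), selectOn = match.arg(selectOn)
  )
  stopifnot(cfg$gensLocalMating >= 0L, cfg$nDams >= 1L, cfg$nBulls >= 1L,
            cfg$nRounds >= 1L, cfg$calvingsPerDam >= 1L, cfg$nQtl >= 1L,
            cfg$h2 > 0, cfg$h2 < 1)
  class(cfg) <- "BreedingConfig"
  cfg
}

# HaploSet for a purebred cohort with constant origin
.purebredHaploSet <- function(H, pos, prefix, population, generation, sex = NULL) {
  n <- nrow(H) %/% 2L
  samples <- data.frame(
    sample_id = sprintf("%s%05d", prefix, seq_len(n)),
    population = population, generation = generation,
    stringsAsFactors = FALSE
  )
  if (!is.null(sex)) samples$sex <- sex
  HaploSet(H, pos, samples)
}

#' Run the crossbreeding program with true origin tracking
#'
#' Simulates the full program described in [breedingConfig()] from a founder
#' panel, tracking the true founder breed (local or exotic) of every allele
#' through each meiosis. The returned object holds, per crossbreeding round,
#' the crossbred cohort, its true origin matrix, and the contemporaneous
#' exotic and local purebred panels.
#'
#' @param founders a founder [HaploSet-class] from [simulateFounders()].
#' @param cfg a [breedingConfig()].
#' @param seed integer seed.
#' @return A list of class \code{"BreedingProgram"} with elements:
#'   \describe{
#'     \item{crossbred}{list of per-round lists with \code{haplos}
#'       (a \code{HaploSet} of the 2 x nDams offspring), \code{origins}
#'       (integer matrix, codes as [boaCodes()]), \code{exoticPanel} and
#'       \code{localPanel} (\code{HaploSet}s).}
#'     \item{pedigree}{\code{data.frame} with id, sire, dam, sex, generation
#'       for every simulated animal.}
#'     \item{trait}{the sampled \code{TraitArchitecture}.}
#'     \item{config}{the \code{BreedingConfig} used.}
#'   }
#' @examples
#' cfg <- founderConfig(nLoci = 60, popSize = 30, ancestralNe = 40,
#'                      breedNe = 20, burnIn = 5, nCandidateLoci = 300)
#' fs <- simulateFounders(cfg, seed = 2)
#' bp <- breedingConfig(gensLocalMating = 2, nDams = 20, nBulls = 5,
#'                      nRounds = 2, nQtl = 10)
#' prog <- runBreedingProgram(fs, bp, seed = 3)
#' mean(prog$crossbred[[1]]$origins == boaCodes()["EXOTIC"]) # F1: exactly 0.5
#' @export
runBreedingProgram <- function(founders, cfg = breedingConfig(), seed = 1L) {
  stopifnot(is(founders, "HaploSet"), inherits(cfg, "BreedingConfig"))
  set.seed(seed)
  pos <- mapPositions(founders)
  mapLen <- attr(pos, "mapLength")
  if (is.null(mapLen)) mapLen <- max(pos)
  pop <- sampleInfo(founders)$population
  exotic <- haploMatrix(subsetIndividuals(founders, pop == "EXOTIC"))
  localH <- haploMatrix(subsetIndividuals(founders, pop != "EXOTIC"))
  nLocal <- nrow(localH) %/% 2L
  nExotic <- nrow(exotic) %/% 2L
  if (nLocal < cfg$nDams) {
    stop("fewer local founders than dams to select")
  }
  if (nExotic < cfg$nBulls) {
    stop("fewer exotic individuals than bulls to draw")
  }

  ped <- list()
  fId <- sampleInfo(founders)$sample_id
  ped[[1L]] <- data.frame(id = fId, sire = NA_character_, dam = NA_character_,
                          sex = NA_character_, generation = "FOUNDER",
                          stringsAsFactors = FALSE)
  localIds <- fId[pop != "EXOTIC"]
  exoticIds <- fId[pop == "EXOTIC"]

  # (1) random mating among the pooled local breeds
  for (g in seq_len(cfg$gensLocalMating)) {
    dams <- sample.int(nLocal, nLocal, replace = TRUE)
    sires <- sample.int(nLocal, nLocal, replace = TRUE)
    localH <- cpp_next_gen(localH, pos, dams - 1L, sires - 1L, mapLen)
    newIds <- sprintf("L%02d_%05d", g, seq_len(nLocal))
    ped[[length(ped) + 1L]] <- data.frame(
      id = newIds, sire = localIds[sires], dam = localIds[dams],
      sex = NA_character_, generation = sprintf("LOCAL_GEN%d", g),
      stringsAsFactors = FALSE
    )
    localIds <- newIds
  }

  # (2) trait-based selection of the dams
  base <- .purebredHaploSet(localH, pos, "LB", "LOCAL", "LOCAL_BASE")
  arch <- sampleTraitArchitecture(base, nQtl = cfg$nQtl, h2 = cfg$h2,
                                  meanDelta = cfg$deltaMean,
                                  varDelta = cfg$deltaVar)
  gv <- geneticValues(dosageMatrix(base), arch)
  phen <- simulatePhenotype(gv, arch$envVar)
  crit <- if (cfg$selectOn == "phenotype") phen else gv
  sexLocal <- sample(rep(c("F", "M"), length.out = nLocal))
  sel <- selectTopFemales(crit, sexLocal, cfg$nDams)
  if (cfg$gensLocalMating >= 1L) {
    ped[[length(ped)]]$sex <- sexLocal # sexes of the last local generation
  }

  damH <- localH[.hapRows(sel), , drop = FALSE]
  damO <- matrix(.LOCAL, nrow(damH), ncol(damH))
  damIds <- localIds[sel]

  crossbred <- vector("list", cfg$nRounds)
  localPure <- localH
  localPureIds <- localIds
  exoticPure <- exotic
  exoticPureIds <- exoticIds

  for (r in seq_len(cfg$nRounds)) {
    # purebred populations advance one generation per round
    damsP <- sample.int(nExotic, nExotic, replace = TRUE)
    siresP <- sample.int(nExotic, nExotic, replace = TRUE)
    exoticPure <- cpp_next_gen(exoticPure, pos, damsP - 1L, siresP - 1L, mapLen)
    newEx <- sprintf("E%02d_%05d", r, seq_len(nExotic))
    ped[[length(ped) + 1L]] <- data.frame(
      id = newEx, sire = exoticPureIds[siresP], dam = exoticPureIds[damsP],
      sex = NA_character_, generation = sprintf("EXOTIC_GEN%d", r),
      stringsAsFactors = FALSE
    )
    exoticPureIds <- newEx

    damsL <- sample.int(nLocal, nLocal, replace = TRUE)
    siresL <- sample.int(nLocal, nLocal, replace = TRUE)
    localPure <- cpp_next_gen(localPure, pos, damsL - 1L, siresL - 1L, mapLen)
    newLoc <- sprintf("P%02d_%05d", r, seq_len(nLocal))
    ped[[length(ped) + 1L]] <- data.frame(
      id = newLoc, sire = localPureIds[siresL], dam = localPureIds[damsL],
      sex = NA_character_, generation = sprintf("LOCAL_PURE_GEN%d", r),
      stringsAsFactors = FALSE
    )
    localPureIds <- newLoc

    # newly imported bulls: a fresh draw from the current exotic generation
    bulls <- sample.int(nExotic, cfg$nBulls)
    nOff <- cfg$calvingsPerDam * cfg$nDams
    damIdx <- rep(seq_len(cfg$nDams), each = cfg$calvingsPerDam)
    sireIdx <- bulls[sample.int(cfg$nBulls, nOff, replace = TRUE)]

    # combined parent pool: dams first, then the exotic purebreds
    parH <- rbind(damH, exoticPure)
    parO <- rbind(damO, matrix(.EXOTIC, nrow(exoticPure), ncol(exoticPure)))
    res <- cpp_next_gen_traced(parH, parO, pos, damIdx - 1L,
                               cfg$nDams + sireIdx - 1L, mapLen)
    offH <- res$haplotypes
    offO <- res$origins
    sexOff <- sample(rep(c("F", "M"), length.out = nOff))
    offIds <- sprintf("X%d_%05d", r, seq_len(nOff))
    gen <- sprintf("CROSSBRED_%d", r)
    ped[[length(ped) + 1L]] <- data.frame(
      id = offIds, sire = exoticPureIds[sireIdx], dam = damIds[damIdx],
      sex = sexOff, generation = gen, stringsAsFactors = FALSE
    )

    samples <- data.frame(sample_id = offIds, population = "CROSSBRED",
                          generation = gen, sex = sexOff,
                          stringsAsFactors = FALSE)
    crossbred[[r]] <- list(
      haplos = HaploSet(offH, pos, samples),
      origins = offO,
      exoticPanel = .purebredHaploSet(exoticPure, pos, sprintf("EP%d_", r),
                                      "EXOTIC", sprintf("EXOTIC_GEN%d", r)),
      localPanel = .purebredHaploSet(localPure, pos, sprintf("LP%d_", r),
                                     "LOCAL", sprintf("LOCAL_PURE_GEN%d", r))
    )

    # all female calves become the dams of the next round
    fem <- which(sexOff == "F")
    damH <- offH[.hapRows(fem), , drop = FALSE]
    damO <- offO[.hapRows(fem), , drop = FALSE]
    damIds <- offIds[fem]
  }

  structure(
    list(crossbred = crossbred, pedigree = do.call(rbind, ped), trait = arch,
         config = cfg),
    class = "BreedingProgram"
  )
}

#' @export
print.BreedingProgram <- function(x, ...) {
  cat(sprintf("BreedingProgram: %d crossbred rounds\n", length(x$crossbred)))
  for (r in seq_along(x$crossbred)) {
    cb <- x$crossbred[[r]]
    cat(sprintf("  round %d: %d offspring, true exotic fraction %.4f\n",
                r, nrow(sampleInfo(cb$haplos)),
                mean(cb$origins == .EXOTIC)))
  }
  invisible(x)
}

#' True exotic allele fraction
#'
#' The fraction of allele cells (haplotype x locus) whose true founder breed
#' is exotic, per individual or per haplotype.
#'
#' @param origins integer origin matrix (codes as [boaCodes()]) with two rows
#'   per individual.
#' @param by \code{"individual"} (default) or \code{"haplotype"}.
#' @return Numeric vector of exotic fractions.
#' @examples
#' o <- rbind(rep(2L, 4), rep(1L, 4)) # an F1: one exotic, one local haplotype
#' trueExoticDosage(o) # 0.5
#' @export
trueExoticDosage <- function(origins, by = c("individual", "haplotype")) {
  by <- match.arg(by)
  ex <- origins == .EXOTIC
  if (by == "haplotype") return(rowMeans(ex))
  n <- nrow(origins) %/% 2L
  (rowMeans(ex)[seq(1L, 2L * n, 2L)] + rowMeans(ex)[seq(2L, 2L * n, 2L)]) / 2
}
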