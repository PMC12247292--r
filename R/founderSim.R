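#' Configuration for the founder-breed simulation
#'
#' Founder breeds are generated under a two-epoch drift model: an ancestral
#' population of \code{ancestralNe} diploids is mated at random for
#' \code{burnIn} generations (building linkage disequilibrium on the
#' chromosome), then splits into an exotic lineage and an indigenous lineage,
#' each founded by a bottleneck of \code{breedNe} individuals. The exotic
#' lineage drifts for \code{splitDepthExotic} generations; the indigenous
#' lineage drifts for \code{splitDepthExotic - splitDepthLocal} generations
#' and then splits into \code{nLocalBreeds} local breeds that drift for a
#' further \code{splitDepthLocal} generations, so local breeds are more
#' closely related to each other than to the exotic breed. Each breed is
#' finally expanded to \code{popSize} individuals by one round of random
#' mating.
#'
#' The default split depths are calibrated (see [calibrateSplit()]) so that
#' the global fixation index between the exotic breed and the pooled local
#' breeds is about 0.09, the level of moderate differentiation typical of
#' exotic dairy versus indigenous African cattle.
#'
#' @param nLoci number of SNPs retained on the chromosome (default 1000).
#' @param nLocalBreeds number of local founder breeds (default 4).
#' @param popSize individuals per founder breed in the emitted panel
#'   (default 500, i.e. 2500 in total with one exotic and four local breeds).
#' @param splitDepthExotic drift generations separating the exotic and
#'   indigenous lineages (calibrated default).
#' @param splitDepthLocal drift generations separating the local breeds from
#'   each other; must be smaller than \code{splitDepthExotic}.
#' @param ancestralNe diploid size of the ancestral population (default 1000).
#' @param breedNe diploid size of each breed lineage after its founding
#'   bottleneck (default 100).
#' @param burnIn random-mating generations in the ancestral population
#'   (default 50).
#' @param nCandidateLoci loci simulated before the allele-frequency filter
#'   (default 1500).
#' @param mapLength chromosome length in Morgans (default 1).
#' @param mafMin minimum minor allele frequency in the pooled founders
#'   (default 0.05).
#' @return A list of class \code{"FounderConfig"}.
#' @seealso [simulateFounders()], [calibrateSplit()]
#' @export
founderConfig <- function(nLoci = 1000L, nLocalBreeds = 4L, popSize = 500L,
                          splitDepthExotic = 21L, splitDepthLocal = 10L,
                          ancestralNe = 1000L, breedNe = 100L, burnIn = 50L,
                          nCandidateLoci = 1500L, mapLength = 1,
                          mafMin = 0.05) {
  cfg <- list(
    nLoci = as.integer(nLoci), nLocalBreeds = as.integer(nLocalBreeds),
    popSize = as.integer(popSize),
    splitDepthExotic = as.integer(splitDepthExotic),
    splitDepthLocal = as.integer(splitDepthLocal),
    ancestralNe = as.integer(ancestralNe), breedNe = as.integer(breedNe),
    burnIn = as.integer(burnIn), nCandidateLoci = as.integer(nCandidateLoci),
    mapLength = as.numeric(mapLength), mafMin = as.numeric(mafMin)
  )
  cfg$nIndividualsTotal <- cfg$popSize * (1L + cfg$nLocalBreeds)
  stopifnot(
    cfg$nLoci > 0L, cfg$nLocalBreeds >= 1L, cfg$popSize >= 2L,
    cfg$splitDepthExotic >= 0L, cfg$splitDepthLocal >= 0L,
    cfg$splitDepthLocal <= cfg$splitDepthExotic,
    cfg$ancestralNe >= 2L, cfg$breedNe >= 2L, cfg$burnIn >= 0L,
    cfg$nCandidateLoci >= cfg$nLoci,
    cfg$mafMin >= 0, cfg$mafMin < 0.5, cfg$mapLength >= 0
  )
  class(cfg) <- "FounderConfig"
  cfg
}

# one generation of random mating at constant (or given) size; parents drawn
# uniformly with replacement
.nextGeneration <- function(H, pos, nOff, mapLength) {
  N <- nrow(H) %/% 2L
  dams <- sample.int(N, nOff, replace = TRUE) - 1L
  sires <- sample.int(N, nOff, replace = TRUE) - 1L
  cpp_next_gen(H, pos, dams, sires, mapLength)
}

.driftPopulation <- function(H, pos, gens, mapLength) {
  N <- nrow(H) %/% 2L
  for (g in seq_len(gens)) H <- .nextGeneration(H, pos, N, mapLength)
  H
}

# founding bottleneck: sample n diploids without replacement
.bottleneck <- function(H, n) {
  keep <- sample.int(nrow(H) %/% 2L, n)
  H[.hapRows(keep), , drop = FALSE]
}

#' Simulate founder breeds
#'
#' Generates phased founder haplotypes for one exotic breed and several local
#' breeds under the drift model described in [founderConfig()]. Loci are
#' filtered to a minor allele frequency of at least \code{mafMin} in the
#' pooled founders and thinned to \code{nLoci} markers spread over the
#' chromosome. The same \code{(cfg, seed)} always yields a bit-identical
#' result.
#'
#' @param cfg a [founderConfig()] object.
#' @param seed integer seed.
#' @return A [HaploSet-class] with populations \code{EXOTIC} and
#'   \code{LOCAL_1 .. LOCAL_k}, generation label \code{"FOUNDER"}.
#' @examples
#' cfg <- founderConfig(nLoci = 50, popSize = 20, ancestralNe = 40,
#'                      breedNe = 20, burnIn = 5, nCandidateLoci = 200)
#' fs <- simulateFounders(cfg, seed = 1)
#' fs
#' @export
simulateFounders <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "FounderConfig"))
  set.seed(seed)
  nc <- cfg$nCandidateLoci
  pos <- sort(stats::runif(nc, 0, cfg$mapLength))
  p0 <- stats::runif(nc, 0.1, 0.9)
  anc <- matrix(stats::rbinom(2L * cfg$ancestralNe * nc, 1L,
                              rep(p0, each = 2L * cfg$ancestralNe)),
                nrow = 2L * cfg$ancestralNe, ncol = nc)
  storage.mode(anc) <- "integer"
  anc <- .driftPopulation(anc, pos, cfg$burnIn, cfg$mapLength)

  tSplit <- cfg$splitDepthExotic - cfg$splitDepthLocal
  exotic <- .driftPopulation(.bottleneck(anc, cfg$breedNe), pos,
                             cfg$splitDepthExotic, cfg$mapLength)
  indig <- .driftPopulation(.bottleneck(anc, cfg$breedNe), pos,
                            tSplit, cfg$mapLength)
  locals <- lapply(seq_len(cfg$nLocalBreeds), function(k) {
    .driftPopulation(.bottleneck(indig, cfg$breedNe), pos,
                     cfg$splitDepthLocal, cfg$mapLength)
  })

  expand <- function(H) .nextGeneration(H, pos, cfg$popSize, cfg$mapLength)
  exotic <- expand(exotic)
  locals <- lapply(locals, expand)

  pooled <- rbind(exotic, do.call(rbind, locals))
  pbar <- colMeans(pooled)
  pass <- which(pmin(pbar, 1 - pbar) >= cfg$mafMin)
  if (length(pass) < cfg$nLoci) {
    stop(sprintf(paste("only %d of %d candidate loci segregate at MAF >= %g;",
                       "raise nCandidateLoci or lower mafMin"),
                 length(pass), nc, cfg$mafMin))
  }
  keep <- pass[round(seq(1, length(pass), length.out = cfg$nLoci))]

  pops <- c("EXOTIC", paste0("LOCAL_", seq_len(cfg$nLocalBreeds)))
  samples <- data.frame(
    sample_id = sprintf("F%04d", seq_len(cfg$nIndividualsTotal)),
    population = rep(pops, each = cfg$popSize),
    generation = "FOUNDER",
    stringsAsFactors = FALSE
  )
  HaploSet(pooled[, keep, drop = FALSE], pos[keep], samples)
}

#' Calibrate the exotic split depth to a target fixation index
#'
#' Performs monotone bisection over the number of drift generations
#' separating the exotic and indigenous lineages until the mean global
#' Hudson FST between the exotic and pooled local founders, averaged over
#' \code{nReps} independent simulations, is within \code{tolerance} of
#' \code{targetFst}. The ratio of \code{splitDepthLocal} to
#' \code{splitDepthExotic} in \code{cfg} is preserved while the depth varies.
#'
#' @param targetFst target fixation index in (0, 1).
#' @param tolerance acceptable absolute deviation of the mean simulated FST.
#' @param cfg a [founderConfig()]; its split depths define the search ratio.
#' @param nReps simulations averaged per depth evaluation (>= 10 recommended).
#' @param depthRange integer search bracket for the exotic depth.
#' @param seed integer seed for the evaluation replicates.
#' @return The calibrated integer split depth, with attribute
#'   \code{"meanFst"} giving its re-simulated mean FST.
#' @export
calibrateSplit <- function(targetFst, tolerance = 0.02, cfg = founderConfig(),
                           nReps = 10L, depthRange = c(0L, 60L), seed = 1L) {
  stopifnot(targetFst > 0, targetFst < 1, tolerance > 0, nReps >= 1L)
  ratio <- if (cfg$splitDepthExotic > 0L) {
    cfg$splitDepthLocal / cfg$splitDepthExotic
  } else 0.5

  evalDepth <- function(depth) {
    vals <- vapply(seq_len(nReps), function(r) {
      c2 <- cfg
      c2$splitDepthExotic <- as.integer(depth)
      c2$splitDepthLocal <- as.integer(round(ratio * depth))
      founderFst(simulateFounders(c2, seed = deriveSeed(seed, "calibrate", r)))
    }, numeric(1L))
    mean(vals)
  }

  lo <- as.integer(depthRange[1L]); hi <- as.integer(depthRange[2L])
  fLo <- evalDepth(lo)
  if (fLo >= targetFst) {
    # already at or above the target with no divergence to remove
    res <- lo; attr(res, "meanFst") <- fLo
    return(res)
  }
  fHi <- evalDepth(hi)
  if (fHi < targetFst) {
    stop(sprintf("search range does not bracket target FST %.3f (FST at depth %d is %.3f)",
                 targetFst, hi, fHi))
  }
  best <- hi; bestF <- fHi
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    fMid <- evalDepth(mid)
    if (abs(fMid - targetFst) < abs(bestF - targetFst)) {
      best <- mid; bestF <- fMid
    }
    if (fMid < targetFst) lo <- mid else hi <- mid
    if (abs(fMid - targetFst) <= tolerance) break
  }
  if (abs(bestF - targetFst) > tolerance) {
    warning(sprintf("calibrated depth %d has mean FST %.4f, outside tolerance %.3f of %.3f",
                    best, bestF, tolerance, targetFst))
  }
  res <- as.integer(best)
  attr(res, "meanFst") <- bestF
  res
}

#' Global FST between the exotic and pooled local founders
#'
#' Convenience wrapper around [fstGlobal()] for a founder [HaploSet-class].
#'
#' @param founders a \code{HaploSet} from [simulateFounders()].
#' @return The global Hudson FST between exotic and pooled local haplotypes.
#' @export
founderFst <- function(founders) {
  pop <- sampleInfo(founders)$population
  ex <- subsetIndividuals(founders, pop == "EXOTIC")
  lo <- subsetIndividuals(founders, pop != "EXOTIC")
  fstGlobal(haploMatrix(ex), haploMatrix(lo))
}
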