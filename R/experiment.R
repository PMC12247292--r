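#' Configuration of the full replicated experiment
#'
#' Bundles the founder, breeding, windowing and consensus settings of one
#' end-to-end evaluation run: per replicate, founders are simulated, the
#' crossbreeding program is run with origin tracking, every crossbred cohort
#' is assigned in all scenarios against its contemporaneous purebred panels,
#' consensus calls are formed, and everything is scored against the true
#' origin.
#'
#' @param founder a [founderConfig()].
#' @param breeding a [breedingConfig()].
#' @param scheme a [phasingScheme()].
#' @param thresholds consensus agreement thresholds (default
#'   [thresholdGrid()]).
#' @param nReplicates number of independent replicates (default 10).
#' @param masterSeed master seed; every stage of every replicate derives its
#'   own stream from it (default 1).
#' @param minMatchFraction optional per-core match threshold, see
#'   [assignCore()].
#' @param allVotesDenominator consensus denominator mode, see
#'   [consensusAllele()].
#' @return A list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(founder = founderConfig(),
                             breeding = breedingConfig(),
                             scheme = phasingScheme(),
                             thresholds = thresholdGrid(),
                             nReplicates = 10L, masterSeed = 1L,
                             minMatchFraction = NULL,
                             allVotesDenominator = FALSE) {
  stopifnot(inherits(founder, "FounderConfig"),
            inherits(breeding, "BreedingConfig"),
            inherits(scheme, "PhasingScheme"),
            nReplicates >= 1L)
  structure(
    list(founder = founder, breeding = breeding, scheme = scheme,
         thresholds = sort(as.numeric(thresholds)),
         nReplicates = as.integer(nReplicates),
         masterSeed = as.integer(masterSeed),
         minMatchFraction = minMatchFraction,
         allVotesDenominator = isTRUE(allVotesDenominator)),
    class = "ExperimentConfig"
  )
}

#' Run the replicated assignment experiment
#'
#' @param cfg an [experimentConfig()].
#' @param verbose print per-replicate progress (default TRUE).
#' @return A list of class \code{"BoaExperiment"} with:
#'   \describe{
#'     \item{coreMetrics}{per replicate x generation x scenario scores
#'       ([scoreCalls()] columns).}
#'     \item{coreCounts}{per replicate x generation x scenario per-haplotype
#'       call counts ([countCalls()] columns).}
#'     \item{consensusMetrics}{per replicate x generation x threshold scores.}
#'     \item{fst}{per-replicate founder FST (exotic vs pooled local).}
#'     \item{config}{the configuration used.}
#'   }
#' @seealso [tableCoreMetrics()], [tableConsensusMetrics()],
#'   [tableGenerationYield()] for the aggregated summary tables.
#' @export
runExperiment <- function(cfg = experimentConfig(), verbose = TRUE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  coreMetrics <- list()
  coreCounts <- list()
  consMetrics <- list()
  fst <- numeric(cfg$nReplicates)
  for (rep in seq_len(cfg$nReplicates)) {
    if (verbose) message(sprintf("replicate %d/%d", rep, cfg$nReplicates))
    founders <- simulateFounders(
      cfg$founder, seed = deriveSeed(cfg$masterSeed, "founders", rep))
    fst[rep] <- founderFst(founders)
    prog <- runBreedingProgram(
      founders, cfg$breeding, seed = deriveSeed(cfg$masterSeed, "program", rep))
    for (r in seq_along(prog$crossbred)) {
      cb <- prog$crossbred[[r]]
      gen <- sprintf("CROSSBRED_%d", r)
      crossHaps <- cb$haplos
      exoPanel <- cb$exoticPanel
      locPanel <- cb$localPanel
      ser <- cfg$scheme$switchErrorRate
      if (ser > 0) {
        sseed <- deriveSeed(cfg$masterSeed, "switch", rep * 100L + r)
        crossHaps <- injectSwitchErrors(crossHaps, ser, seed = sseed)
        exoPanel <- injectSwitchErrors(exoPanel, ser)
        locPanel <- injectSwitchErrors(locPanel, ser)
      }
      asg <- assignAll(crossHaps, exoPanel, locPanel, cfg$scheme,
                       minMatchFraction = cfg$minMatchFraction,
                       generation = gen)
      ev <- .evaluateCohort(asg, cb$origins, cfg$thresholds,
                            cfg$allVotesDenominator)
      meta <- data.frame(replicate = rep, generation = gen,
                         stringsAsFactors = FALSE)
      coreMetrics[[length(coreMetrics) + 1L]] <- cbind(meta, ev$core)
      coreCounts[[length(coreCounts) + 1L]] <- cbind(meta, ev$counts)
      consMetrics[[length(consMetrics) + 1L]] <- cbind(meta, ev$consensus)
    }
  }
  out <- list(
    coreMetrics = do.call(rbind, coreMetrics),
    coreCounts = do.call(rbind, coreCounts),
    consensusMetrics = do.call(rbind, consMetrics),
    fst = fst,
    config = cfg
  )
  rownames(out$coreMetrics) <- NULL
  rownames(out$coreCounts) <- NULL
  rownames(out$consensusMetrics) <- NULL
  class(out) <- "BoaExperiment"
  out
}

# Single pass over the scenarios of one cohort: per-scenario scores and call
# counts, plus vote accumulation so the consensus can be scored per threshold
# without materialising a call matrix per threshold. Semantics are identical
# to scoreAssignments()/consensusCalls()/scoreConsensus(), which the test
# suite verifies.
.evaluateCohort <- function(asg, truth, thresholds, allVotesDenominator) {
  scen <- asg@scenarios
  ns <- nrow(scen)
  nH <- nrow(asg@calls[[1L]])
  nl <- asg@nLoci
  nE <- matrix(0L, nH, nl)
  nL <- matrix(0L, nH, nl)
  core <- vector("list", ns)
  cnts <- vector("list", ns)
  for (s in seq_len(ns)) {
    cl <- expandCalls(asg, s)
    core[[s]] <- cbind(scen[s, , drop = FALSE], scoreCalls(cl, truth))
    cnts[[s]] <- cbind(scen[s, , drop = FALSE], countCalls(cl))
    nE <- nE + (cl == .EXOTIC)
    nL <- nL + (cl == .LOCAL)
  }
  voted <- nE + nL
  denom <- if (allVotesDenominator) matrix(ns, nH, nl) else voted
  leader <- matrix(.MISSING, nH, nl)
  leader[nE > nL] <- .EXOTIC
  leader[nL > nE] <- .LOCAL
  cnt <- pmax(nE, nL)
  agree <- ifelse(denom > 0L, cnt / denom, 0)
  okBase <- voted > 0L & (cnt > denom / 2)
  leaderCorrect <- okBase & (leader == truth)
  n <- as.numeric(nH) * nl
  consRows <- lapply(thresholds, function(tau) {
    assigned <- okBase & agree >= tau
    nAssigned <- sum(assigned)
    nCorrect <- sum(leaderCorrect & agree >= tau)
    data.frame(
      threshold = tau,
      pct_correct = 100 * nCorrect / n,
      pct_incorrect = 100 * (nAssigned - nCorrect) / n,
      pct_unassigned = 100 * (n - nAssigned) / n,
      yield = nAssigned / n,
      accuracy = if (nAssigned > 0) nCorrect / nAssigned else NA_real_
    )
  })
  out <- list(core = do.call(rbind, core), counts = do.call(rbind, cnts),
              consensus = do.call(rbind, consRows))
  for (i in seq_along(out)) rownames(out[[i]]) <- NULL
  out
}

#' @export
print.BoaExperiment <- function(x, ...) {
  cat(sprintf("BoaExperiment: %d replicates\n", x$config$nReplicates))
  cat(sprintf("mean founder FST: %.4f\n", mean(x$fst)))
  t4 <- tableCoreMetrics(x)
  cat(sprintf("core-based means: %%correct %.2f, %%incorrect %.2f, %%unassigned %.2f, accuracy %.3f\n",
              mean(t4$pct_correct), mean(t4$pct_incorrect),
              mean(t4$pct_unassigned), mean(t4$accuracy)))
  t5 <- tableConsensusMetrics(x)
  cat(sprintf("consensus means:  %%correct %.2f, %%incorrect %.2f, %%unassigned %.2f, accuracy %.3f\n",
              mean(t5$pct_correct), mean(t5$pct_incorrect),
              mean(t5$pct_unassigned), mean(t5$accuracy)))
  invisible(x)
}

.aggMean <- function(df, cols, by) {
  stats::aggregate(df[cols], df[by], mean)
}

#' Core-length summary of assignment performance
#'
#' Percentages of alleles correctly assigned, incorrectly assigned, and
#' unassigned for each core length, averaged over window modes, generations
#' and replicates, with the per-core-length accuracy.
#'
#' @param x a \code{BoaExperiment} from [runExperiment()].
#' @return A \code{data.frame} with one row per core length.
#' @export
tableCoreMetrics <- function(x) {
  t4 <- .aggMean(x$coreMetrics,
                 c("pct_correct", "pct_incorrect", "pct_unassigned"),
                 "core_length")
  t4$accuracy <- t4$pct_correct / (t4$pct_correct + t4$pct_incorrect)
  t4
}

#' Threshold summary of consensus performance
#'
#' @param x a \code{BoaExperiment}.
#' @return A \code{data.frame} with one row per agreement threshold.
#' @export
tableConsensusMetrics <- function(x) {
  t5 <- .aggMean(x$consensusMetrics,
                 c("pct_correct", "pct_incorrect", "pct_unassigned"),
                 "threshold")
  t5$accuracy <- t5$pct_correct / (t5$pct_correct + t5$pct_incorrect)
  t5
}

#' Per-generation yield summary
#'
#' Mean numbers of alleles per haplotype (out of the chromosome's loci)
#' assigned local, exotic, or left unassigned in each crossbred generation,
#' averaged over core lengths, window modes and replicates.
#'
#' @param x a \code{BoaExperiment}.
#' @return A \code{data.frame} with one row per crossbred generation.
#' @export
tableGenerationYield <- function(x) {
  .aggMean(x$coreCounts, c("n_local", "n_exotic", "n_unassigned", "yield"),
           "generation")
}
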