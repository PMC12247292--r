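#' Default agreement thresholds
#'
#' @return The ten agreement thresholds 0.50, 0.55, ..., 0.95.
#' @export
thresholdGrid <- function() seq(0.50, 0.95, by = 0.05)

#' Consensus call for one allele from scenario votes
#'
#' Merges the per-scenario calls for one haplotype-locus cell: the leading
#' breed among the non-missing votes wins if it holds a strict majority of
#' the non-missing votes and its agreement (leader count over non-missing
#' votes) reaches the threshold; otherwise the consensus is missing. With
#' \code{allVotesDenominator = TRUE} the agreement is computed over all votes
#' including missing ones.
#'
#' @param votes integer vector of call codes (see [boaCodes()]).
#' @param threshold agreement threshold in \code{[0.5, 1)}.
#' @param allVotesDenominator logical; count missing votes in the agreement
#'   denominator (default \code{FALSE}).
#' @return A single call code.
#' @examples
#' consensusAllele(c(rep(1L, 12), rep(2L, 8)), 0.50) # LOCAL
#' consensusAllele(c(rep(1L, 12), rep(2L, 8)), 0.65) # MISSING
#' @export
consensusAllele <- function(votes, threshold, allVotesDenominator = FALSE) {
  if (!length(votes)) stop("empty vote set")
  stopifnot(threshold >= 0.5, threshold < 1)
  nL <- sum(votes == .LOCAL)
  nE <- sum(votes == .EXOTIC)
  tot <- if (allVotesDenominator) length(votes) else nL + nE
  if (nL + nE == 0L || nL == nE) return(.MISSING)
  leader <- if (nL > nE) .LOCAL else .EXOTIC
  cnt <- max(nL, nE)
  if (cnt / tot >= threshold && cnt > tot / 2) leader else .MISSING
}

#' Consensus calls over all scenarios at every threshold
#'
#' Applies the rule of [consensusAllele()] to every haplotype-locus cell of a
#' [BoaAssignment-class], pooling the votes of its scenarios (by default the
#' 20 combinations of ten core lengths and two window modes), at each
#' agreement threshold.
#'
#' @param assignment a [BoaAssignment-class].
#' @param thresholds numeric vector of agreement thresholds (default
#'   [thresholdGrid()]).
#' @param allVotesDenominator logical, see [consensusAllele()].
#' @return A [ConsensusCalls-class].
#' @export
consensusCalls <- function(assignment, thresholds = thresholdGrid(),
                           allVotesDenominator = FALSE) {
  stopifnot(is(assignment, "BoaAssignment"))
  thresholds <- sort(as.numeric(thresholds))
  stopifnot(all(thresholds >= 0.5), all(thresholds < 1))
  ns <- nrow(assignment@scenarios)
  nH <- nrow(assignment@calls[[1L]])
  nl <- assignment@nLoci
  nE <- matrix(0L, nH, nl)
  nL <- matrix(0L, nH, nl)
  for (s in seq_len(ns)) {
    cl <- expandCalls(assignment, s)
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
  majority <- cnt > denom / 2
  calls <- lapply(thresholds, function(tau) {
    out <- leader
    out[!(voted > 0L & majority & agree >= tau)] <- .MISSING
    out
  })
  new("ConsensusCalls", calls = calls, thresholds = thresholds)
}

#' Per-locus consensus calls at one threshold
#'
#' @param consensus a [ConsensusCalls-class].
#' @param threshold one of its thresholds.
#' @return Integer matrix (haplotypes x loci) of call codes.
#' @export
consensusAt <- function(consensus, threshold) {
  stopifnot(is(consensus, "ConsensusCalls"))
  i <- match(TRUE, abs(consensus@thresholds - threshold) < 1e-9)
  if (is.na(i)) stop("threshold not present in this ConsensusCalls object")
  consensus@calls[[i]]
}
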