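#' Score a call matrix against the true origin matrix
#'
#' Counts, over all haplotype-locus cells, the alleles whose call equals the
#' true founder breed (correct), carries the other breed (incorrect), or is
#' missing (unassigned). Percentages share one denominator (all cells), so
#' \code{pct_correct + pct_incorrect + pct_unassigned == 100} exactly.
#' Accuracy is correct over assigned cells and is \code{NA} when nothing is
#' assigned.
#'
#' @param calls integer matrix of call codes (haplotypes x loci).
#' @param truth integer origin matrix of the same shape (codes
#'   \code{LOCAL}/\code{EXOTIC} of [boaCodes()]).
#' @return A one-row \code{data.frame} with \code{pct_correct},
#'   \code{pct_incorrect}, \code{pct_unassigned}, \code{yield},
#'   \code{accuracy}.
#' @examples
#' truth <- matrix(c(1L, 2L), 2, 4)
#' scoreCalls(truth, truth) # 100% correct
#' @export
scoreCalls <- function(calls, truth) {
  if (!identical(dim(calls), dim(truth))) {
    stop("calls and truth are not aligned on haplotype x locus")
  }
  n <- length(truth)
  nCorrect <- sum(calls == truth)
  nMissing <- sum(calls == .MISSING)
  nIncorrect <- n - nCorrect - nMissing
  assigned <- nCorrect + nIncorrect
  data.frame(
    pct_correct = 100 * nCorrect / n,
    pct_incorrect = 100 * nIncorrect / n,
    pct_unassigned = 100 * nMissing / n,
    yield = assigned / n,
    accuracy = if (assigned > 0) nCorrect / assigned else NA_real_
  )
}

#' Score a BoaAssignment per scenario
#'
#' @param assignment a [BoaAssignment-class].
#' @param truth integer origin matrix aligned with the assigned haplotypes.
#' @return A \code{data.frame} with one row per scenario: \code{core_length},
#'   \code{offset} and the columns of [scoreCalls()].
#' @export
scoreAssignments <- function(assignment, truth) {
  stopifnot(is(assignment, "BoaAssignment"))
  scen <- assignment@scenarios
  rows <- lapply(seq_len(nrow(scen)), function(s) {
    cbind(scen[s, , drop = FALSE],
          scoreCalls(expandCalls(assignment, s), truth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score consensus calls per threshold
#'
#' @param consensus a [ConsensusCalls-class].
#' @param truth integer origin matrix aligned with the haplotypes.
#' @return A \code{data.frame} with one row per threshold.
#' @export
scoreConsensus <- function(consensus, truth) {
  stopifnot(is(consensus, "ConsensusCalls"))
  rows <- lapply(seq_along(consensus@thresholds), function(i) {
    cbind(data.frame(threshold = consensus@thresholds[i]),
          scoreCalls(consensus@calls[[i]], truth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global Wright's FST between two groups of haplotypes
#'
#' Multi-locus fixation index as a ratio of sums over loci. The default is
#' the Hudson estimator: per-locus numerator
#' \eqn{(p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, averaged over loci before
#' taking the ratio. Loci monomorphic in both groups combined are excluded.
#' \code{estimator = "wc"} instead uses the Weir-Cockerham variance
#' components for haploid samples.
#'
#' @param A,B 0/1 haplotype matrices (rows = haplotypes) over the same loci,
#'   each with at least 2 rows.
#' @param estimator \code{"hudson"} (default) or \code{"wc"}.
#' @return The global FST estimate.
#' @examples
#' A <- matrix(0L, 10, 5); B <- matrix(1L, 10, 5)
#' fstGlobal(A, B) # 1: fixed differences at every locus
#' @export
fstGlobal <- function(A, B, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (ncol(A) != ncol(B)) stop("groups do not share the same loci")
  if (nrow(A) < 2L || nrow(B) < 2L) stop("need at least 2 haplotypes per group")
  nA <- nrow(A); nB <- nrow(B)
  pA <- colMeans(A); pB <- colMeans(B)
  poly <- !((pA == 0 & pB == 0) | (pA == 1 & pB == 1))
  if (!any(poly)) stop("all loci are monomorphic in both groups")
  pA <- pA[poly]; pB <- pB[poly]
  if (estimator == "hudson") {
    num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
    return(mean(num) / mean(den))
  }
  # Weir-Cockerham variance components for haploid (allele-level) samples,
  # two populations (r = 2)
  n <- c(nA, nB)
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / sum(n)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- pbar * (1 - pbar)
  a <- nbar / nc * (s2 - (hbar - s2 * (r - 1) / r) / (nbar - 1))
  b <- nbar / (nbar - 1) * (hbar - s2 * (r - 1) / r)
  sum(a) / sum(a + b)
}

#' Principal components of a genotype dosage matrix
#'
#' Column-centred singular value decomposition of the dosage matrix, as used
#' to visualise the genetic structure of founders and crossbreds.
#'
#' @param dosage individuals x loci numeric matrix of allele dosages.
#' @param nComp number of components to return (default 3).
#' @return A matrix (individuals x nComp) of principal-component coordinates,
#'   with the proportion of variance explained in attribute
#'   \code{"varExplained"}.
#' @export
pcaGenotypes <- function(dosage, nComp = 3L) {
  if (nrow(dosage) < 3L) stop("need at least 3 individuals")
  X <- scale(dosage, center = TRUE, scale = FALSE)
  if (all(abs(X) < .Machine$double.eps)) stop("dosage matrix has zero variance")
  nComp <- min(nComp, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = nComp, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(nComp)], nComp, nComp)
  colnames(scores) <- paste0("PC", seq_len(nComp))
  attr(scores, "varExplained") <- (sv$d^2 / sum(sv$d^2))[seq_len(nComp)]
  scores
}

#' Per-haplotype allele-call counts
#'
#' Average numbers of alleles per haplotype (out of the chromosome's loci)
#' called local, exotic, or left unassigned -- the per-generation yield
#' summary of the assignment.
#'
#' @param calls integer call matrix (haplotypes x loci).
#' @return A one-row \code{data.frame} with \code{n_local}, \code{n_exotic},
#'   \code{n_unassigned} (mean counts per haplotype) and \code{yield}.
#' @export
countCalls <- function(calls) {
  nl <- ncol(calls)
  data.frame(
    n_local = mean(rowSums(calls == .LOCAL)),
    n_exotic = mean(rowSums(calls == .EXOTIC)),
    n_unassigned = mean(rowSums(calls == .MISSING)),
    yield = mean(calls != .MISSING)
  )
}
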