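#' Define core windows over the chromosome
#'
#' Cores are half-open windows of consecutive SNP indices that tile the
#' chromosome exactly once. Without offset the windows are
#' \code{[0, L), [L, 2L), ...}; with offset the first window is half a core
#' long, \code{[0, L/2)}, followed by full windows, so the two modes stagger
#' core boundaries by 50\% of the core length. A final partial window keeps
#' coverage complete when \code{nLoci} is not a multiple of \code{L}.
#'
#' @param nLoci number of loci on the chromosome.
#' @param coreLength core length in SNPs (\code{0 < coreLength <= nLoci}).
#' @param offset logical; stagger the windows by half a core length.
#' @return A \code{data.frame} with columns \code{core_id}, \code{start}
#'   (0-based inclusive), \code{stop} (exclusive), \code{length},
#'   \code{mode}.
#' @examples
#' makeCores(1000, 100, offset = FALSE)$start # 0, 100, ..., 900
#' nrow(makeCores(1000, 100, offset = TRUE))  # 11 windows
#' @export
makeCores <- function(nLoci, coreLength, offset = FALSE) {
  nLoci <- as.integer(nLoci)
  coreLength <- as.integer(coreLength)
  if (coreLength <= 0L) stop("coreLength must be positive")
  if (coreLength > nLoci) stop("coreLength exceeds the number of loci")
  starts <- if (offset) {
    first <- coreLength %/% 2L
    if (first >= nLoci) 0L else c(0L, seq.int(first, nLoci - 1L, by = coreLength))
  } else {
    seq.int(0L, nLoci - 1L, by = coreLength)
  }
  stops <- c(starts[-1L], nLoci)
  data.frame(
    core_id = seq_along(starts),
    start = starts, stop = stops, length = stops - starts,
    mode = if (offset) "offset" else "no_offset",
    stringsAsFactors = FALSE
  )
}

#' The default phasing scheme
#'
#' Ten core lengths (100 to 280 SNPs in steps of 20) crossed with the two
#' window modes (with and without 50\% offset) give the 20 per-replicate
#' assignment scenarios.
#'
#' @param coreLengths integer vector of core lengths.
#' @param switchErrorRate per-heterozygous-site switch probability applied to
#'   the input haplotypes before assignment (default 0: perfect phasing).
#' @return A list of class \code{"PhasingScheme"} with a \code{scenarios}
#'   \code{data.frame} (columns \code{core_length}, \code{offset}).
#' @export
phasingScheme <- function(coreLengths = seq(100L, 280L, by = 20L),
                          switchErrorRate = 0) {
  stopifnot(all(coreLengths > 0L), switchErrorRate >= 0, switchErrorRate <= 1)
  scenarios <- expand.grid(core_length = as.integer(coreLengths),
                           offset = c(FALSE, TRUE),
                           KEEP.OUT.ATTRS = FALSE)
  scenarios <- scenarios[order(scenarios$core_length, scenarios$offset), ]
  rownames(scenarios) <- NULL
  structure(list(scenarios = scenarios,
                 switchErrorRate = as.numeric(switchErrorRate)),
            class = "PhasingScheme")
}

#' Inject switch errors into phased haplotypes
#'
#' Emulates imperfect statistical phasing with the classic switch-error
#' model: at each heterozygous locus of an individual, independently with
#' probability \code{rate}, the maternal/paternal assignment from that locus
#' onward is flipped. Genotypes (the unordered allele pair at each locus)
#' are unchanged.
#'
#' @param haploset a [HaploSet-class].
#' @param rate switch probability per heterozygous site in \code{[0, 1]}.
#' @param seed optional integer seed.
#' @return A \code{HaploSet} with the same genotypes and possibly switched
#'   haplotypes.
#' @export
injectSwitchErrors <- function(haploset, rate, seed = NULL) {
  stopifnot(is(haploset, "HaploSet"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(haploset)
  H <- haploMatrix(haploset)
  n <- nrow(H) %/% 2L
  for (i in seq_len(n)) {
    a <- H[2L * i - 1L, ]
    b <- H[2L * i, ]
    het <- which(a != b)
    if (!length(het)) next
    sw <- het[stats::runif(length(het)) < rate]
    if (!length(sw)) next
    # cumulative flips: phase state changes at each switch point
    flip <- (findInterval(seq_along(a), sw) %% 2L) == 1L
    na <- ifelse(flip, b, a)
    nb <- ifelse(flip, a, b)
    H[2L * i - 1L, ] <- na
    H[2L * i, ] <- nb
  }
  HaploSet(H, mapPositions(haploset), sampleInfo(haploset))
}
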