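#' Build a purebred haplotype library for one core
#'
#' Collects the distinct haplotype sequences observed in a purebred panel
#' over the core window \code{[start, stop)}, with the number of panel
#' haplotypes carrying each sequence.
#'
#' @param purebred a [HaploSet-class] of purebred reference animals.
#' @param start,stop 0-based half-open locus bounds of the core (e.g. one
#'   row of [makeCores()]).
#' @param breed label stored with the library (e.g. \code{"EXOTIC"}).
#' @return A [HaplotypeLibrary-class].
#' @examples
#' h <- matrix(rep(c(0L, 1L), each = 4), 4, 2) # two identical pairs
#' hs <- HaploSet(h, c(0.1, 0.2),
#'                data.frame(sample_id = c("a", "b"), population = "EXOTIC",
#'                           generation = "FOUNDER"))
#' buildLibrary(hs, 0, 2, "EXOTIC")
#' @export
buildLibrary <- function(purebred, start, stop, breed = "PUREBRED") {
  stopifnot(is(purebred, "HaploSet"))
  if (nHaplotypes(purebred) == 0L) stop("empty purebred panel")
  stopifnot(start >= 0L, stop > start, stop <= nLoci(purebred))
  X <- haploMatrix(purebred)[, (start + 1L):stop, drop = FALSE]
  key <- .keyOf(X)
  tab <- table(factor(key, levels = unique(key)))
  entries <- X[!duplicated(key), , drop = FALSE]
  new("HaplotypeLibrary", entries = entries, counts = as.integer(tab),
      breed = breed, start = as.integer(start), stop = as.integer(stop))
}

#' Hamming distance between two haplotype sequences
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return The number of mismatching positions.
#' @examples
#' mismatches(c(0L, 1L, 1L), c(1L, 1L, 0L)) # 2
#' @export
mismatches <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length")
  sum(a != b)
}

#' Best match of a target haplotype in a library
#'
#' @param target 0/1 vector with the core's width.
#' @param lib a [HaplotypeLibrary-class].
#' @return A list with \code{min} (the minimum Hamming distance over library
#'   entries) and \code{nmin} (how many distinct entries attain it).
#' @export
bestMatch <- function(target, lib) {
  stopifnot(is(lib, "HaplotypeLibrary"))
  if (nrow(lib@entries) == 0L) stop("empty haplotype library")
  if (length(target) != ncol(lib@entries)) {
    stop("target length does not match the library's core width")
  }
  res <- cpp_min_hamming(matrix(as.integer(target), nrow = 1L), lib@entries)
  list(min = res$min[1L], nmin = res$nmin[1L])
}

#' Assign one core haplotype to a breed
#'
#' Implements the fewest-mismatch rule: the target is assigned to the breed
#' whose library holds the closer match; if both libraries contain an equally
#' good match the call is missing. Optionally a winning library must also
#' match at least a fraction \code{minMatchFraction} of the core's SNPs
#' (i.e. \code{1 - min/width >= minMatchFraction}), otherwise the call is
#' missing.
#'
#' @param target 0/1 vector over the core.
#' @param libExotic,libLocal [HaplotypeLibrary-class] objects over the same
#'   core.
#' @param minMatchFraction optional minimum matching fraction in \code{[0,1]};
#'   \code{NULL} (default) disables the check.
#' @return One of \code{boaCodes()}: \code{EXOTIC}, \code{LOCAL} or
#'   \code{MISSING} (as an integer code).
#' @export
assignCore <- function(target, libExotic, libLocal, minMatchFraction = NULL) {
  if (libExotic@start != libLocal@start || libExotic@stop != libLocal@stop) {
    stop("libraries are defined on different cores")
  }
  mE <- bestMatch(target, libExotic)$min
  mL <- bestMatch(target, libLocal)$min
  .callFromDistances(mE, mL, length(target), minMatchFraction)
}

# vectorised decision rule shared by assignCore and assignAll
.callFromDistances <- function(mE, mL, width, minMatchFraction = NULL) {
  call <- rep(.MISSING, length(mE))
  call[mE < mL] <- .EXOTIC
  call[mL < mE] <- .LOCAL
  if (!is.null(minMatchFraction)) {
    win <- pmin(mE, mL)
    call[call != .MISSING & (1 - win / width) < minMatchFraction] <- .MISSING
  }
  call
}

#' Assign breed origin to all crossbred haplotypes in all scenarios
#'
#' For every scenario of the phasing scheme (core length x window mode) the
#' chromosome is tiled into cores, per-core haplotype libraries are built
#' from the two purebred panels (local breeds pooled into one panel), and
#' each crossbred core haplotype is assigned by the fewest-mismatch rule of
#' [assignCore()]. The per-core call applies to (is broadcast over) every
#' locus of the core.
#'
#' Matching is exact but fast: haplotypes are deduplicated per core, targets
#' found verbatim in exactly one library are called without a distance scan
#' (a zero-distance match in only one library always wins; in both, the tie
#' rule gives missing), and the rest are matched with a packed-bit Hamming
#' kernel.
#'
#' @param crossbreds [HaploSet-class] of crossbred animals.
#' @param exoticPanel,localPanel purebred reference [HaploSet-class]s sharing
#'   the crossbreds' locus set.
#' @param scheme a [phasingScheme()].
#' @param minMatchFraction optional per-core minimum matching fraction
#'   (see [assignCore()]).
#' @param generation label stored with the result.
#' @return A [BoaAssignment-class].
#' @export
assignAll <- function(crossbreds, exoticPanel, localPanel,
                      scheme = phasingScheme(), minMatchFraction = NULL,
                      generation = "CROSSBRED") {
  stopifnot(is(crossbreds, "HaploSet"), is(exoticPanel, "HaploSet"),
            is(localPanel, "HaploSet"))
  nl <- nLoci(crossbreds)
  if (nLoci(exoticPanel) != nl || nLoci(localPanel) != nl) {
    stop("panels and crossbreds do not share the same locus set")
  }
  H <- haploMatrix(crossbreds)
  EP <- haploMatrix(exoticPanel)
  LP <- haploMatrix(localPanel)
  scen <- scheme$scenarios
  calls <- vector("list", nrow(scen))
  coresList <- vector("list", nrow(scen))
  mmf <- if (is.null(minMatchFraction)) -1 else as.numeric(minMatchFraction)
  for (s in seq_len(nrow(scen))) {
    cores <- makeCores(nl, scen$core_length[s], scen$offset[s])
    cmat <- matrix(.MISSING, nrow(H), nrow(cores))
    for (ci in seq_len(nrow(cores))) {
      cmat[, ci] <- cpp_assign_window(H, EP, LP, cores$start[ci],
                                      cores$stop[ci], mmf)
    }
    calls[[s]] <- cmat
    coresList[[s]] <- cores
  }
  new("BoaAssignment", calls = calls, scenarios = scen, cores = coresList,
      nLoci = as.integer(nl), generation = generation)
}

#' Expand per-core calls to per-locus calls
#'
#' @param assignment a [BoaAssignment-class].
#' @param scenario scenario index (row of \code{assignment@scenarios}).
#' @return Integer matrix (haplotypes x loci) with each core's call broadcast
#'   to its loci.
#' @export
expandCalls <- function(assignment, scenario) {
  stopifnot(is(assignment, "BoaAssignment"))
  cores <- assignment@cores[[scenario]]
  loc2core <- findInterval(seq_len(assignment@nLoci) - 1L, cores$start)
  assignment@calls[[scenario]][, loc2core, drop = FALSE]
}
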