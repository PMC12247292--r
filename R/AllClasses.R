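#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib crossBOA, .registration = TRUE
NULL

#' Integer codes for breed-origin calls
#'
#' All origin matrices and call matrices in the package use the same integer
#' coding: \code{0} = missing/unassigned, \code{1} = local, \code{2} = exotic.
#'
#' @return A named integer vector \code{c(MISSING = 0, LOCAL = 1, EXOTIC = 2)}.
#' @examples
#' boaCodes()
#' @export
boaCodes <- function() c(MISSING = 0L, LOCAL = 1L, EXOTIC = 2L)

.MISSING <- 0L
.LOCAL <- 1L
.EXOTIC <- 2L

#' HaploSet: a set of phased haplotypes with map positions and sample labels
#'
#' The central container for phased biallelic haplotypes. The haplotype
#' matrix stores one row per haplotype, two consecutive rows per individual
#' (maternal row first), entries in \{0, 1\}. Locus positions are genetic-map
#' positions in Morgans, strictly increasing. The sample table carries one
#' row per individual with at least columns \code{sample_id},
#' \code{population} and \code{generation}.
#'
#' @slot haplotypes integer matrix of 0/1 entries, \code{2 * nrow(samples)}
#'   rows and one column per locus.
#' @slot positions numeric vector of genetic-map positions (Morgans), one per
#'   locus, strictly increasing.
#' @slot samples \code{data.frame} with one row per individual.
#'
#' @seealso [HaploSet()] for the constructor, [haploMatrix()],
#'   [mapPositions()], [sampleInfo()] for accessors.
#' @name HaploSet-class
#' @aliases HaploSet-class
#' @exportClass HaploSet
setClass("HaploSet",
  representation(
    haplotypes = "matrix",
    positions = "numeric",
    samples = "data.frame"
  )
)

setValidity("HaploSet", function(object) {
  h <- object@haplotypes
  msg <- character()
  if (!is.integer(h)) {
    msg <- c(msg, "haplotypes must be an integer matrix")
  } else if (length(h) && !all(h == 0L | h == 1L)) {
    msg <- c(msg, "haplotype entries must be 0 or 1")
  }
  if (nrow(h) != 2L * nrow(object@samples)) {
    msg <- c(msg, "haplotypes must have exactly two rows per sample")
  }
  if (length(object@positions) != ncol(h)) {
    msg <- c(msg, "positions must have one entry per locus")
  }
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0)) {
    msg <- c(msg, "positions must be strictly increasing")
  }
  need <- c("sample_id", "population", "generation")
  if (!all(need %in% names(object@samples))) {
    msg <- c(msg, paste("samples must contain columns:",
                        paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaploSet
#'
#' @param haplotypes 0/1 matrix with two rows per individual (maternal row
#'   first). Coerced to integer storage.
#' @param positions numeric vector of map positions in Morgans, strictly
#'   increasing, one per column of \code{haplotypes}.
#' @param samples \code{data.frame} with one row per individual and columns
#'   \code{sample_id}, \code{population}, \code{generation} (further columns,
#'   e.g. \code{sex}, are kept).
#' @return A [HaploSet-class] object.
#' @examples
#' h <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
#' hs <- HaploSet(h, c(0.1, 0.2),
#'                data.frame(sample_id = "a", population = "LOCAL_1",
#'                           generation = "FOUNDER"))
#' hs
#' @export
HaploSet <- function(haplotypes, positions, samples) {
  storage.mode(haplotypes) <- "integer"
  new("HaploSet", haplotypes = haplotypes, positions = as.numeric(positions),
      samples = samples)
}

#' HaplotypeLibrary: unique purebred haplotypes within one core
#'
#' The set of distinct haplotype sequences observed in one purebred reference
#' panel over one core window, each with the number of panel haplotypes
#' carrying it.
#'
#' @slot entries integer matrix of unique 0/1 rows, one column per locus in
#'   the core.
#' @slot counts integer vector of observation counts, one per entry;
#'   \code{sum(counts)} equals the number of contributing panel haplotypes.
#' @slot breed single character, e.g. \code{"EXOTIC"} or \code{"LOCAL"}.
#' @slot start,stop 0-based half-open locus bounds of the core.
#'
#' @seealso [buildLibrary()]
#' @name HaplotypeLibrary-class
#' @aliases HaplotypeLibrary-class
#' @exportClass HaplotypeLibrary
setClass("HaplotypeLibrary",
  representation(
    entries = "matrix",
    counts = "integer",
    breed = "character",
    start = "integer",
    stop = "integer"
  )
)

setValidity("HaplotypeLibrary", function(object) {
  msg <- character()
  if (nrow(object@entries) != length(object@counts)) {
    msg <- c(msg, "one count per entry required")
  }
  if (length(object@counts) && any(object@counts < 1L)) {
    msg <- c(msg, "counts must be >= 1")
  }
  if (anyDuplicated(apply(object@entries, 1L, paste0, collapse = ""))) {
    msg <- c(msg, "entries must be pairwise distinct")
  }
  if (object@stop - object@start != ncol(object@entries)) {
    msg <- c(msg, "core width must equal entry width")
  }
  if (length(msg)) msg else TRUE
})

#' BoaAssignment: per-core breed-origin calls across scenarios
#'
#' Holds the calls of [assignAll()]: for each scenario (a core length
#' crossed with a window mode) an integer matrix with one row per crossbred
#' haplotype and one column per core, coded as in [boaCodes()]. Per-locus
#' calls are obtained by broadcasting each core's call to its loci (see
#' [expandCalls()]).
#'
#' @slot calls list of integer call matrices, one per scenario.
#' @slot scenarios \code{data.frame} with columns \code{core_length} and
#'   \code{offset}, one row per scenario.
#' @slot cores list of core tables (as returned by [makeCores()]), parallel
#'   to \code{calls}.
#' @slot nLoci integer, number of loci on the chromosome.
#' @slot generation character label of the crossbred cohort assigned.
#'
#' @name BoaAssignment-class
#' @aliases BoaAssignment-class
#' @exportClass BoaAssignment
setClass("BoaAssignment",
  representation(
    calls = "list",
    scenarios = "data.frame",
    cores = "list",
    nLoci = "integer",
    generation = "character"
  )
)

setValidity("BoaAssignment", function(object) {
  msg <- character()
  ns <- nrow(object@scenarios)
  if (length(object@calls) != ns || length(object@cores) != ns) {
    msg <- c(msg, "calls and cores must have one element per scenario")
  }
  for (i in seq_along(object@calls)) {
    if (ncol(object@calls[[i]]) != nrow(object@cores[[i]])) {
      msg <- c(msg, sprintf("scenario %d: one call column per core required", i))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusCalls: per-allele consensus calls at each agreement threshold
#'
#' @slot calls list of integer matrices (haplotypes x loci), one per
#'   threshold, coded as in [boaCodes()].
#' @slot thresholds numeric vector of agreement thresholds in \code{[0.5, 1)}.
#'
#' @seealso [consensusCalls()]
#' @name ConsensusCalls-class
#' @aliases ConsensusCalls-class
#' @exportClass ConsensusCalls
setClass("ConsensusCalls",
  representation(
    calls = "list",
    thresholds = "numeric"
  )
)

setValidity("ConsensusCalls", function(object) {
  msg <- character()
  if (length(object@calls) != length(object@thresholds)) {
    msg <- c(msg, "one call matrix per threshold required")
  }
  if (is.unsorted(object@thresholds, strictly = TRUE)) {
    msg <- c(msg, "thresholds must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})
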