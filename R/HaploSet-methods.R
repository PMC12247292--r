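#' @describeIn HaploSet-class number of haplotype rows (two per individual).
#' @param x,object a \code{HaploSet}.
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)

#' @describeIn HaploSet-class number of loci.
#' @export
nLoci <- function(x) ncol(x@haplotypes)

#' @describeIn HaploSet-class the 0/1 haplotype matrix.
#' @export
haploMatrix <- function(x) x@haplotypes

#' @describeIn HaploSet-class genetic-map positions in Morgans.
#' @export
mapPositions <- function(x) x@positions

#' @describeIn HaploSet-class per-individual sample table.
#' @export
sampleInfo <- function(x) x@samples

#' Subset a HaploSet by individuals
#'
#' @param x a \code{HaploSet}.
#' @param individuals integer or logical index over individuals (not
#'   haplotype rows).
#' @return A \code{HaploSet} with the selected individuals.
#' @export
subsetIndividuals <- function(x, individuals) {
  idx <- seq_len(nrow(x@samples))[individuals]
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  HaploSet(x@haplotypes[rows, , drop = FALSE], x@positions,
           x@samples[idx, , drop = FALSE])
}

#' Combine two HaploSets sharing the same loci
#'
#' @param x,y \code{HaploSet} objects with identical positions.
#' @return The row-concatenated \code{HaploSet}.
#' @export
bindHaploSets <- function(x, y) {
  if (!isTRUE(all.equal(x@positions, y@positions))) {
    stop("HaploSets do not share the same locus set")
  }
  HaploSet(rbind(x@haplotypes, y@haplotypes), x@positions,
           rbind(x@samples, y@samples))
}

#' Genotype dosage matrix of a HaploSet
#'
#' @param x a \code{HaploSet}.
#' @return Integer matrix (individuals x loci) of allele dosages in
#'   \{0, 1, 2\}.
#' @export
dosageMatrix <- function(x) {
  n <- nrow(x@samples)
  h <- x@haplotypes
  h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

setMethod("show", "HaploSet", function(object) {
  cat(sprintf("HaploSet: %d individuals (%d haplotypes) x %d loci\n",
              nrow(object@samples), nrow(object@haplotypes),
              ncol(object@haplotypes)))
  pops <- table(object@samples$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  cat(sprintf("map: %.3f Morgans (%g .. %g)\n",
              diff(range(object@positions)),
              min(object@positions), max(object@positions)))
})

setMethod("show", "HaplotypeLibrary", function(object) {
  cat(sprintf("HaplotypeLibrary (%s): %d unique haplotypes from %d observed, core [%d, %d)\n",
              object@breed, nrow(object@entries), sum(object@counts),
              object@start, object@stop))
})

setMethod("show", "BoaAssignment", function(object) {
  cat(sprintf("BoaAssignment: %d haplotypes, %d loci, %d scenarios (%s)\n",
              if (length(object@calls)) nrow(object@calls[[1L]]) else 0L,
              object@nLoci, nrow(object@scenarios), object@generation))
  cat("core lengths:",
      paste(sort(unique(object@scenarios$core_length)), collapse = ", "), "\n")
})

setMethod("show", "ConsensusCalls", function(object) {
  cat(sprintf("ConsensusCalls: %d haplotypes x %d loci at %d thresholds (%s)\n",
              if (length(object@calls)) nrow(object@calls[[1L]]) else 0L,
              if (length(object@calls)) ncol(object@calls[[1L]]) else 0L,
              length(object@thresholds),
              paste(format(object@thresholds), collapse = ", ")))
})

#' Library entries and counts
#'
#' @param x a \code{HaplotypeLibrary}.
#' @return \code{libraryEntries}: the matrix of unique haplotypes;
#'   \code{libraryCounts}: their observation counts.
#' @export
libraryEntries <- function(x) x@entries

#' @rdname libraryEntries
#' @export
libraryCounts <- function(x) x@counts
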