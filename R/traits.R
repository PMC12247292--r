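#' Sample a trait architecture with additive and dominance effects
#'
#' Draws QTL positions and effects for a single quantitative trait. Additive
#' effects are standard normal; dominance degrees \eqn{\delta_i} are drawn
#' from Normal(meanDelta, varDelta) and dominance effects are
#' \eqn{d_i = \delta_i |a_i|}. The environmental variance is solved from the
#' additive and dominance variance realized in the supplied base population
#' (assuming Hardy-Weinberg and linkage equilibrium at the QTL) so that the
#' narrow-sense heritability equals \code{h2}.
#'
#' @param base a [HaploSet-class] representing the base population in which
#'   heritability is anchored (typically the pooled local founders).
#' @param nQtl number of QTL, drawn uniformly among the loci.
#' @param h2 target narrow-sense heritability in (0, 1), default 0.3.
#' @param meanDelta mean dominance degree (default 0.1).
#' @param varDelta variance of the dominance degree (default 0.1).
#' @param seed optional integer seed.
#' @return A list of class \code{"TraitArchitecture"} with elements
#'   \code{qtl} (locus indices), \code{a}, \code{delta}, \code{d},
#'   \code{envVar}, \code{addVar}, \code{domVar}, \code{h2}.
#' @examples
#' cfg <- founderConfig(nLoci = 50, popSize = 20, ancestralNe = 40,
#'                      breedNe = 20, burnIn = 5, nCandidateLoci = 200)
#' fs <- simulateFounders(cfg, seed = 1)
#' arch <- sampleTraitArchitecture(fs, nQtl = 10, seed = 1)
#' arch$envVar
#' @export
sampleTraitArchitecture <- function(base, nQtl = 100L, h2 = 0.3,
                                    meanDelta = 0.1, varDelta = 0.1,
                                    seed = NULL) {
  stopifnot(is(base, "HaploSet"), nQtl >= 1L, nQtl <= nLoci(base),
            h2 > 0, h2 < 1, varDelta >= 0)
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample.int(nLoci(base), nQtl))
  a <- stats::rnorm(nQtl)
  delta <- stats::rnorm(nQtl, meanDelta, sqrt(varDelta))
  d <- delta * abs(a)
  p <- colMeans(haploMatrix(base)[, qtl, drop = FALSE])
  q <- 1 - p
  alpha <- a + d * (q - p) # average effect of an allele substitution
  addVar <- sum(2 * p * q * alpha^2)
  domVar <- sum((2 * p * q * d)^2)
  if (addVar <= 0) {
    stop("no additive genetic variance at the sampled QTL; population may be monomorphic")
  }
  envVar <- max(addVar / h2 - addVar - domVar, 0)
  structure(
    list(qtl = qtl, a = a, delta = delta, d = d, envVar = envVar,
         addVar = addVar, domVar = domVar, h2 = h2),
    class = "TraitArchitecture"
  )
}

#' Genetic value of one individual
#'
#' The additive-plus-dominance value
#' \eqn{\sum_i a_i (x_i - 1) + d_i \mathbf{1}(x_i = 1)} over the QTL, where
#' \eqn{x_i \in \{0, 1, 2\}} is the allele dosage.
#'
#' @param haplopair 2 x nLoci matrix of 0/1 alleles (the individual's two
#'   haplotypes).
#' @param arch a \code{TraitArchitecture}.
#' @return The genetic value (numeric scalar).
#' @examples
#' arch <- structure(list(qtl = 1L, a = 2, d = 0.5, envVar = 0),
#'                   class = "TraitArchitecture")
#' geneticValue(rbind(1L, 0L), arch) # dosage 1 -> d = 0.5
#' @export
geneticValue <- function(haplopair, arch) {
  stopifnot(nrow(haplopair) == 2L, all(haplopair %in% c(0L, 1L)))
  if (max(arch$qtl) > ncol(haplopair)) {
    stop("haplopair has fewer loci than the trait architecture expects")
  }
  x <- haplopair[1L, arch$qtl] + haplopair[2L, arch$qtl]
  sum(arch$a * (x - 1) + arch$d * (x == 1L))
}

#' Genetic values for a whole population
#'
#' @param dosage individuals x loci dosage matrix (see [dosageMatrix()]).
#' @param arch a \code{TraitArchitecture}.
#' @return Numeric vector of genetic values, one per individual.
#' @export
geneticValues <- function(dosage, arch) {
  X <- dosage[, arch$qtl, drop = FALSE]
  as.numeric((X - 1) %*% arch$a + (X == 1L) %*% arch$d)
}

#' Phenotype as genetic value plus normal environmental noise
#'
#' @param gv numeric vector of genetic values.
#' @param envVar environmental variance (>= 0).
#' @param seed optional integer seed.
#' @return Numeric vector of phenotypes.
#' @export
simulatePhenotype <- function(gv, envVar, seed = NULL) {
  stopifnot(envVar >= 0)
  if (!is.null(seed)) set.seed(seed)
  gv + stats::rnorm(length(gv), 0, sqrt(envVar))
}

#' Select the top females on phenotype
#'
#' Returns the indices of the \code{n} females with the highest selection
#' criterion; ties are broken by index so the choice is deterministic.
#'
#' @param criterion numeric vector (phenotype or genetic value), one per
#'   individual.
#' @param sex character vector of \code{"F"}/\code{"M"}, one per individual.
#' @param n number of females to select.
#' @return Integer vector of \code{n} selected individual indices.
#' @export
selectTopFemales <- function(criterion, sex, n) {
  stopifnot(length(criterion) == length(sex))
  fem <- which(sex == "F")
  if (length(fem) < n) {
    stop(sprintf("only %d females available, %d requested", length(fem), n))
  }
  fem[order(-criterion[fem], fem)][seq_len(n)]
}
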