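---
title: "Methods: breed origin of alleles by windowed haplotype-library matching"
author: "crossBOA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breed origin of alleles by windowed haplotype-library matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossBOA)
```

## The problem

Smallholder dairy herds in low- and middle-income countries are typically
crosses between imported high-yielding ("exotic") sires and indigenous
("local") cows, accumulated over repeated rounds of bull importation with
little or no pedigree recording. For breed-specific genetic evaluation and
for managing the balance between productivity and local adaptation, one
wants to know, for every allele a crossbred animal carries, which founder
breed it descends from — the *breed origin of alleles* (BOA). crossBOA
implements a pedigree-free BOA assignment algorithm driven entirely by
phased genotypes and purebred reference panels, together with a stochastic
simulator of the crossbreeding system that tracks the true origin of every
allele, so the algorithm's yield and accuracy can be measured exactly.

## The assignment algorithm

The chromosome is tiled into *cores*: half-open windows of `L` consecutive
SNPs (`makeCores()`). Within each core, the distinct haplotype sequences
observed in each purebred panel form that breed's *haplotype library*
(`buildLibrary()`); the four local breeds are pooled into a single local
panel. Each crossbred haplotype is compared against both libraries by
Hamming distance and assigned to the breed whose library contains the
closest entry; if both libraries achieve the same minimum distance the call
is *missing* (`assignCore()`). The per-core call is broadcast to every locus
in the core, giving per-allele calls.

Assignment is repeated across a grid of core lengths (100–280 SNPs in steps
of 20) and two window *modes* — the plain tiling, and an *offset* tiling
whose first window is half a core long so all later boundaries shift by
50% of the core length (`phasingScheme()`). The 20 resulting scenarios vote
per allele; the *consensus* call at agreement threshold $\tau$ is the
majority breed among the non-missing votes, accepted only when it holds a
strict majority and a fraction $\ge \tau$ of those votes, otherwise missing
(`consensusAllele()`, thresholds 0.50–0.95).

Two readings of "threshold" are supported. The default attaches the
threshold to the consensus agreement, which reproduces the observed behaviour
that at $\tau = 0.5$ essentially nothing is unassigned — something that
could not happen if missing votes counted against the leader, which is why
the agreement denominator is the non-missing vote count (the
`allVotesDenominator` flag provides the alternative reading). Independently,
a per-core *minimum match fraction* can require the winning library to match
at least a fraction of the core's SNPs (`minMatchFraction`), off by default.

Performance scoring (`scoreCalls()`) compares calls to the tracked truth
with a single denominator — all haplotype × locus cells — so that
%correct + %incorrect + %unassigned = 100 exactly; *yield* is the assigned
fraction and *accuracy* is correct over assigned, reported as missing when
nothing is assigned.

## The simulated study system

`runExperiment()` evaluates the algorithm on a simulated smallholder
program:

1. **Founder breeds** (`simulateFounders()`). One exotic and four local
   breeds of 500 diploids each (2500 in total) on one chromosome of 1000
   biallelic SNPs spanning a 1-Morgan map with uniform recombination.
2. **Local admixture**: ten generations of random mating among the pooled
   2000 local animals.
3. **Selection**: a single quantitative trait with 100 QTL, additive
   effects standard normal, dominance degrees $\delta_i \sim N(0.1, 0.1)$
   and $d_i = \delta_i |a_i|$, environmental variance solved so narrow-sense
   $h^2 = 0.3$ in the base herd. The 1000 phenotypically best cows become
   the dams. (A flag switches the criterion to true genetic value; phenotype
   is the default because with $h^2 = 0.3$ phenotypic selection is the
   operationally meaningful choice.)
4. **Crossbreeding**: five rounds; in each, 25 bulls are freshly drawn from
   the current exotic purebred generation ("newly imported"), every dam
   calves twice with the sire drawn uniformly per mating, giving 2000
   offspring at a forced 1000/1000 sex ratio; all 1000 female calves replace
   the dams. No further selection is applied after the initial one, because
   *all* female calves are retained as replacements. Both purebred
   populations are propagated in parallel at constant size by random mating
   and serve as the contemporaneous reference panels of each round.
5. **Truth tracking**: meiosis draws a Poisson number of crossovers (mean =
   map length in Morgans), breakpoints uniform, no interference; the origin
   rows are cut at exactly the same breakpoints as the haplotypes, so every
   allele's founder breed is known by construction.

The default experiment runs this in 10 independent replicates, with every
stage drawing from a stream derived from one master seed (`deriveSeed()`),
so replicates are independent and the whole experiment is reproducible
bit-for-bit.

## The founder demography and its calibration

The real demographic history behind such populations is unknown in detail;
what is well characterised is the *differentiation level* between exotic
dairy and indigenous African cattle, a global fixation index of about 0.09.
The founder generator therefore uses a deliberately simple two-epoch drift
model whose one free quantity — the split depth — is calibrated to that
fixation index:

* an ancestral population of `ancestralNe` = 1000 diploids is mated at
  random for `burnIn` = 50 generations, building linkage disequilibrium on
  the chromosome while retaining high ancestral haplotype diversity;
* the exotic and indigenous lineages are founded by bottlenecks of
  `breedNe` = 100 diploids (a recent effective size typical of commercial
  cattle breeds) and drift for `splitDepthExotic` generations; the
  indigenous lineage splits again into four local breeds at half that
  depth, so local breeds are mutually closer than any is to the exotic
  breed;
* candidate loci start at ascertained-SNP-like frequencies (uniform on
  0.1–0.9), and after the final expansion to 500 diploids per breed the
  1000 markers are chosen among loci with pooled minor allele frequency
  ≥ 0.05, spread evenly over the map.

`calibrateSplit()` bisects the split depth until the mean Hudson FST between
exotic and pooled local founders, over replicate simulations, hits the
target. With the default target of 0.09 this gives 21 generations
(re-simulated mean FST ≈ 0.086), which is the package default
(`founderConfig()`).

**What the generator does and does not emulate.** It reproduces the
differentiation level, the breed topology (one exotic vs four related local
breeds), realistic linkage disequilibrium at the 1-Morgan scale, and
library-relevant haplotype sharing within breeds. It does *not* reproduce
the deep coalescent ancestry of real cattle: because the ancestral pool
starts in linkage equilibrium, core-length haplotypes are essentially never
shared *between* breeds, so equal-best-match ties — the main source of
missing calls on real or coalescent-simulated data — are rare here.
Consequently the package's default experiment shows noticeably lower
unassigned rates (well under 1%) than would be seen with coalescent
founders or imperfectly phased data, and the unassigned rate is not
concentrated in the first crossbred generation. Passing the accuracy and
correctness checks here therefore demonstrates the algorithm's behaviour
given faithful panels, not its robustness to deep shared ancestry; the
`switchErrorRate` knob (a classic switch-error model that flips the
maternal/paternal phase from a heterozygous site onward) is provided to
re-introduce phasing-driven ambiguity for sensitivity analyses.

## Numerical and design choices

* **Tie-breaking** is never silent: equal best matches give a missing call;
  equal vote counts give a missing consensus; selection ties are broken by
  individual index so selection is deterministic.
* **Partial terminal windows** are kept (the last core of a tiling may be
  shorter than `L`), so every locus is covered exactly once in every
  scenario.
* **Library counts** are recorded but unused in matching: the tie rule is
  about match quality, not frequency.
* **Degenerate inputs** fail loudly: empty panels or libraries, unphased or
  multiallelic VCF records (named by record), fewer segregating loci than
  requested (with advice to raise the mutation supply or lower the MAF
  cutoff), traits with zero additive variance, and non-bracketing
  calibration ranges are all explicit errors.
* **FST estimator**: Hudson's ratio-of-averages (numerator
  $(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$, denominator
  $p_1(1-p_2)+p_2(1-p_1)$), chosen for its frequency-level transparency and
  near-unbiasedness; a Weir–Cockerham variant is available via
  `estimator = "wc"`. Loci monomorphic across both groups are excluded.
* **PCA** is the column-centred SVD of the dosage matrix, equivalent to
  `prcomp` up to component sign.
* **Performance**: gamete formation and window matching run in C++; core
  haplotypes are packed 64 loci to a machine word so a Hamming distance is
  a handful of XOR/popcount operations, targets are deduplicated per window,
  and a target found verbatim in exactly one library is called without any
  distance scan (a zero-distance match cannot be beaten, only tied). The
  test suite proves this fast path bit-identical to a plain R
  loop over `mismatches()`/`bestMatch()`/`assignCore()`.

## Problem sizes

The default experiment — 10 replicates × (founder simulation, 15+ breeding
generations, 5 crossbred cohorts of 2000 animals × 1000 loci, 20 assignment
scenarios, 10 consensus thresholds) — completes in roughly 6–8 minutes on
one core. Unit tests run on miniatures (tens of individuals, tens of loci)
whose expected outcomes are computed by independent brute-force oracles in
the test code itself.

## Known limitations

* Assignment uses no linkage information beyond the core window and no
  probabilistic model of ancestry; it is exact nearest-library matching, as
  designed.
* Statistical phasing is not performed; inputs are either truly phased
  simulator output or user-supplied phased VCFs, optionally corrupted by
  the switch-error model. Phasing yield of any particular phasing tool is
  out of scope.
* The drift-based founder model understates between-breed haplotype
  sharing, as discussed above; absolute unassigned rates on real data will
  be higher than in the default simulation.
* Only a biallelic, single-chromosome marker panel is modelled; extending
  to multiple chromosomes is a matter of running per chromosome.
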