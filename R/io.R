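#' Decode integer call codes to letters
#'
#' @param calls integer vector or matrix of call codes (see [boaCodes()]).
#' @return Character object of the same shape with \code{"M"}, \code{"L"},
#'   \code{"E"}.
#' @export
decodeCalls <- function(calls) {
  out <- c("M", "L", "E")[as.integer(calls) + 1L]
  if (is.matrix(calls)) dim(out) <- dim(calls)
  out
}

# Morgans -> integer bp for VCF POS, assuming 1 cM per Mb (1 Morgan = 100 Mb);
# collisions after rounding are pushed right so POS stays strictly increasing.
.posToBp <- function(pos) {
  bp <- as.integer(round(pos * 1e8)) + 1L
  bp <- cummax(bp + c(0L, cumsum(diff(bp) <= 0L)))
  while (any(d <- diff(bp) <= 0L)) bp[which(d) + 1L] <- bp[which(d)] + 1L
  bp
}

#' Write a HaploSet as a phased VCF v4.2
#'
#' One contig, GT-only records with "|"-separated alleles. Map positions in
#' Morgans are converted to base pairs at 1 cM/Mb. A sample sheet
#' (tab-separated: sample_id, population, generation) is written alongside
#' when \code{sampleSheet} is given.
#'
#' @param haploset a [HaploSet-class].
#' @param path output VCF path (plain text).
#' @param chrom contig name (default "1").
#' @param sampleSheet optional path for the companion sample sheet TSV.
#' @return \code{path}, invisibly.
#' @export
writePhasedVcf <- function(haploset, path, chrom = "1", sampleSheet = NULL) {
  stopifnot(is(haploset, "HaploSet"))
  H <- haploMatrix(haploset)
  info <- sampleInfo(haploset)
  n <- nrow(info)
  bp <- .posToBp(mapPositions(haploset))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=crossBOA",
    sprintf("##contig=<ID=%s,length=%d>", chrom, max(bp) + 1L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", info$sample_id), collapse = "\t")
  ), con)
  mat <- H[seq(1L, 2L * n, 2L), , drop = FALSE]
  pat <- H[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(mat, "|", pat), nrow = n) # individuals x loci
  lines <- vapply(seq_along(bp), function(j) {
    paste(c(chrom, bp[j], sprintf("snp%d", j), "A", "B", ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t")
  }, character(1L))
  writeLines(lines, con)
  if (!is.null(sampleSheet)) writeSampleSheet(info, sampleSheet)
  invisible(path)
}

#' Write / read a sample sheet
#'
#' Tab-separated, one row per individual with at least sample_id, population
#' and generation.
#'
#' @param samples \code{data.frame} of per-individual metadata.
#' @param path file path.
#' @return \code{writeSampleSheet}: \code{path} invisibly;
#'   \code{readSampleSheet}: the \code{data.frame}.
#' @export
writeSampleSheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a phased VCF into a HaploSet
#'
#' Accepts a single-contig VCF with fully phased GT ("|" separator) and
#' biallelic records only; any unphased ("/") or multiallelic record raises
#' an error naming the offending record. Base-pair positions are converted
#' back to Morgans at 1 cM/Mb.
#'
#' @param path VCF path.
#' @param sampleSheet a \code{data.frame} (or path to a TSV) with columns
#'   \code{sample_id}, \code{population}, \code{generation}; sample ids must
#'   match the VCF's sample columns.
#' @return A [HaploSet-class].
#' @export
readPhasedVcf <- function(path, sampleSheet) {
  if (is.character(sampleSheet)) sampleSheet <- readSampleSheet(sampleSheet)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (length(unique(fix[, "CHROM"])) > 1L) {
    stop("expected a single contig")
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop(sprintf("multiallelic record(s) at row(s) %s (e.g. %s:%s)",
                 paste(utils::head(which(multi), 5L), collapse = ", "),
                 fix[which(multi)[1L], "CHROM"], fix[which(multi)[1L], "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype at record %d (%s:%s), sample %s",
                 bad[["row"]], fix[bad[["row"]], "CHROM"],
                 fix[bad[["row"]], "POS"], colnames(gt)[bad[["col"]]]))
  }
  if (any(is.na(gt))) stop("missing genotypes are not supported")
  samples <- colnames(gt)
  m <- match(samples, sampleSheet$sample_id)
  if (anyNA(m)) {
    stop(sprintf("sample sheet lacks: %s",
                 paste(samples[is.na(m)], collapse = ", ")))
  }
  alleles <- strsplit(as.vector(gt), "|", fixed = TRUE)
  if (any(lengths(alleles) != 2L)) stop("genotypes must be diploid")
  am <- matrix(as.integer(unlist(alleles)), nrow = 2L)
  if (any(am > 1L)) stop("only biallelic 0/1 alleles are supported")
  nl <- nrow(gt); n <- length(samples)
  H <- matrix(0L, 2L * n, nl)
  # gt is loci x samples; alleles are column-major over loci within sample
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * nl + 1L):(i * nl)
    H[2L * i - 1L, ] <- am[1L, cols]
    H[2L * i, ] <- am[2L, cols]
  }
  pos <- (as.numeric(fix[, "POS"]) - 1) / 1e8
  HaploSet(H, pos, sampleSheet[m, , drop = FALSE])
}

#' Write the core scheme as a CSV
#'
#' @param nLoci number of loci.
#' @param scheme a [phasingScheme()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCoreScheme <- function(nLoci, scheme, path) {
  scen <- scheme$scenarios
  rows <- lapply(seq_len(nrow(scen)), function(s) {
    cbind(core_length = scen$core_length[s],
          makeCores(nLoci, scen$core_length[s], scen$offset[s]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-allele calls as a long-format TSV
#'
#' One row per haplotype x locus x scenario with the call as L/E/M. Intended
#' for modest problem sizes; the full default experiment is better summarised
#' with the metric tables.
#'
#' @param assignment a [BoaAssignment-class].
#' @param haploset the assigned [HaploSet-class] (for individual ids).
#' @param path output TSV path.
#' @param replicate replicate id recorded in the file (default 1).
#' @return \code{path}, invisibly.
#' @export
writeCallsTsv <- function(assignment, haploset, path, replicate = 1L) {
  stopifnot(is(assignment, "BoaAssignment"), is(haploset, "HaploSet"))
  info <- sampleInfo(haploset)
  nl <- assignment@nLoci
  ids <- rep(info$sample_id, each = 2L)
  hapno <- rep(c(0L, 1L), nrow(info))
  scen <- assignment@scenarios
  blocks <- lapply(seq_len(nrow(scen)), function(s) {
    cl <- expandCalls(assignment, s)
    data.frame(
      replicate = replicate,
      generation = assignment@generation,
      individual = rep(ids, times = nl),
      haplotype = rep(hapno, times = nl),
      locus = rep(seq_len(nl), each = length(ids)),
      core_length = scen$core_length[s],
      mode = ifelse(scen$offset[s], "offset", "no_offset"),
      call = decodeCalls(as.vector(cl)),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a true origin matrix as TSV
#'
#' @param origins integer origin matrix (two rows per individual).
#' @param ids character vector of haplotype row ids.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeOriginMatrix <- function(origins, ids, path) {
  stopifnot(length(ids) == nrow(origins))
  df <- data.frame(haplotype_id = ids, decodeCalls(origins),
                   stringsAsFactors = FALSE)
  names(df) <- c("haplotype_id", sprintf("locus%d", seq_len(ncol(origins))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pedigree as CSV
#'
#' @param program a \code{BreedingProgram} from [runBreedingProgram()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(program, path) {
  utils::write.csv(program$pedigree, path, row.names = FALSE)
  invisible(path)
}

#' Write the experiment result bundle
#'
#' Writes the raw per-replicate metric tables and the three aggregated
#' summary tables as CSV files into \code{dir}. Re-running on the same
#' bundle overwrites the same files (idempotent).
#'
#' @param x a \code{BoaExperiment} from [runExperiment()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeExperimentOutputs <- function(x, dir) {
  stopifnot(inherits(x, "BoaExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(x$coreMetrics, "core_metrics.csv")
  w(x$coreCounts, "core_counts.csv")
  w(x$consensusMetrics, "consensus_metrics.csv")
  w(data.frame(replicate = seq_along(x$fst), fst = x$fst), "founder_fst.csv")
  w(tableCoreMetrics(x), "table_core_lengths.csv")
  w(tableConsensusMetrics(x), "table_thresholds.csv")
  w(tableGenerationYield(x), "table_generations.csv")
  invisible(dir)
}
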