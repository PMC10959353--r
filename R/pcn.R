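#' Mean depth per family on a consensus library
#'
#' Mean per-base depth over each consensus sequence from all-hits
#' alignments: secondary records contribute at every reported location, so
#' reads from any genomic copy of a family accumulate on its consensus.
#' Families with no alignments get depth 0.
#'
#' @param aln Alignments of reads to the consensus library.
#' @param consensus_lengths Named vector of consensus lengths (one per
#'   family).
#' @return Named numeric vector of mean depths.
#' @export
consensus_depth <- function(aln, consensus_lengths) {
  ds <- depth_summary(aln, consensus_lengths)
  setNames(ds$mean_depth, ds$rname)
}

#' Genome-wide mean depth
#'
#' Mean depth over all reference positions (zero-depth positions included).
#' Intended for best-hit alignments of the same read set to the whole
#' reference assembly: one location per read, so the value estimates true
#' sequencing depth even on repeat-rich genomes.
#'
#' @param aln Alignments of reads to the reference genome.
#' @param genome_len Total reference length in bp (> 0).
#' @return Mean depth (0 if no alignments).
#' @export
genome_mean_depth <- function(aln, genome_len) {
  if (genome_len <= 0) stop("genome length must be > 0")
  if (!nrow(aln)) return(0)
  sum(aln$end - aln$start) / genome_len
}

#' Proxy copy number from depth ratio
#'
#' pCN = (mean depth on the family consensus) / (genome-wide mean depth).
#' The consensus mean already corrects for consensus length, and the ratio
#' cancels read length and sequencing depth, leaving copies per haploid
#' genome equivalent.
#'
#' @param consensus_depth_f Named vector of per-family mean consensus
#'   depths.
#' @param genome_depth Genome-wide mean depth (> 0).
#' @return Named numeric vector of pCN estimates.
#' @export
estimate_pcn <- function(consensus_depth_f, genome_depth) {
  if (genome_depth <= 0)
    stop("genome mean depth must be > 0 for pCN normalization")
  consensus_depth_f / genome_depth
}

#' Estimate pCNs for one accession from reads
#'
#' Convenience wrapper running the full per-accession recipe: all-hits
#' alignment of the reads to the consensus library, best-hit alignment to
#' the reference genome, then the depth-ratio pCN.
#'
#' @param reads A `read_set` (typically [wgs_reads()] output or real WGS).
#' @param families A `family_panel` (or named character vector of
#'   consensus sequences).
#' @param genome A `synthetic_genome` (or named character vector of
#'   chromosomes).
#' @param ... Passed to [naive_align()].
#' @return list with `pcn` (named vector), `consensus_depth`,
#'   `genome_depth`.
#' @export
accession_pcn <- function(reads, families, genome, ...) {
  cons <- if (inherits(families, "family_panel"))
    family_consensus(families) else as_ref_vector(families)
  refs <- as_ref_vector(genome)
  aln_cons <- naive_align(reads, cons, all_hits = TRUE, ...)
  aln_gen <- naive_align(reads, refs, all_hits = FALSE, ...)
  cd <- consensus_depth(aln_cons, nchar(cons))
  gd <- genome_mean_depth(aln_gen, sum(nchar(refs)))
  list(pcn = estimate_pcn(cd, gd), consensus_depth = cd, genome_depth = gd)
}
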