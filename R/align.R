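#' Align reads with exact-seed / ungapped-extension
#'
#' A deliberately simple read aligner: exact k-mer seeding on both strands
#' followed by greedy ungapped extension with a mismatch budget
#' (`max_mm_per100` mismatches per 100 bp of read), soft-clipping the
#' unextendable tails. With `all_hits = TRUE` every passing location is
#' reported (the all-alignments convention used for repeat coverage
#' estimation); otherwise only the best placement per read (fewest
#' mismatches, then longest block). It is not a general-purpose aligner —
#' no gaps, no quality model — but on substitution-only synthetic data it
#' recovers truth positions exactly, which is what the pipeline's tests
#' require. External SAM alignments can be substituted anywhere via
#' [read_sam()].
#'
#' Long query sequences (assembled contigs) are supported: each accepted
#' extension is one matched block, so a query straddling a breakpoint
#' yields one row per block (split-alignment semantics).
#'
#' @param reads A `read_set`, named character vector, or plain character
#'   vector of sequences.
#' @param reference Named character vector, DNAStringSet, FASTA path or
#'   `synthetic_genome`.
#' @param seed_len Exact seed length (k-mer, <= 32).
#' @param stride Distance between successive seed positions on the read.
#' @param max_mm_per100 Mismatch budget per 100 bp of query.
#' @param all_hits Report all passing locations, not just the best.
#' @param min_span Minimum matched block length to report.
#' @return data.frame with columns read_id, rname, start, end (0-based
#'   half-open), strand, nm, clip_left, clip_right, n_clipped, mapq,
#'   is_duplicate (all FALSE; see [mark_duplicates()]).
#' @export
naive_align <- function(reads, reference, seed_len = 31, stride = 7,
                        max_mm_per100 = 2, all_hits = TRUE,
                        min_span = seed_len) {
  refs <- as_ref_vector(reference)
  if (any(nchar(refs) < seed_len))
    stop("reference shorter than seed_len")
  if (inherits(reads, "read_set") || is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- reads$seq
  } else {
    seqs <- unname(reads)
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%d", seq_along(reads))
  }
  if (!length(seqs)) return(empty_alignments())
  hits <- cpp_align(unname(refs), seqs, as.integer(seed_len),
                    as.integer(stride), max_mm_per100 / 100,
                    isTRUE(all_hits), as.integer(min_span))
  if (!nrow(hits)) return(empty_alignments())
  n_per_read <- table(hits$read_idx)
  df <- data.frame(
    read_id = ids[hits$read_idx],
    rname = names(refs)[hits$ref_idx],
    start = hits$start, end = hits$end, strand = hits$strand,
    nm = hits$nm, clip_left = hits$clip_left, clip_right = hits$clip_right,
    n_clipped = hits$clip_left + hits$clip_right,
    mapq = ifelse(as.vector(n_per_read[as.character(hits$read_idx)]) > 1,
                  0L, 60L),
    is_duplicate = FALSE, stringsAsFactors = FALSE)
  df[order(df$rname, df$start, df$read_id), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

empty_alignments <- function() {
  data.frame(read_id = character(0), rname = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             nm = integer(0), clip_left = integer(0),
             clip_right = integer(0), n_clipped = integer(0),
             mapq = integer(0), is_duplicate = logical(0),
             stringsAsFactors = FALSE)
}

#' Flag duplicate alignments
#'
#' Records identical in (reference, start, end, strand) beyond the first
#' encountered are flagged `is_duplicate`, mirroring the
#' ignore-duplicates convention of coverage tools: on a circular template
#' amplified and sheared, fragments with identical breakpoints are treated
#' as one molecule.
#'
#' @param aln Alignment data.frame.
#' @return The same data.frame with `is_duplicate` filled in.
#' @export
mark_duplicates <- function(aln) {
  if (!nrow(aln)) return(aln)
  key <- paste(aln$rname, aln$start, aln$end, aln$strand, sep = "\r")
  aln$is_duplicate <- duplicated(key)
  aln
}

#' Per-reference depth summary from alignments
#'
#' Counts every alignment record at every matched base (the all-hits
#' coverage convention), including zero-depth positions in the mean.
#'
#' @param aln Alignment data.frame.
#' @param ref_lengths Named vector of reference lengths.
#' @return data.frame with rname, length, total_bases (summed per-base
#'   depth) and mean_depth.
#' @export
depth_summary <- function(aln, ref_lengths) {
  stopifnot(!is.null(names(ref_lengths)))
  tot <- setNames(numeric(length(ref_lengths)), names(ref_lengths))
  if (nrow(aln)) {
    widths <- tapply(aln$end - aln$start, aln$rname, sum)
    tot[names(widths)] <- widths
  }
  data.frame(rname = names(ref_lengths),
             length = as.numeric(ref_lengths),
             total_bases = as.numeric(tot),
             mean_depth = as.numeric(tot) / as.numeric(ref_lengths),
             stringsAsFactors = FALSE)
}

#' Per-base depth along one reference
#'
#' @param aln Alignment data.frame.
#' @param rname Reference name.
#' @param ref_len Reference length.
#' @param dedup Drop records flagged `is_duplicate`.
#' @return Integer vector of per-base depth, length `ref_len`.
#' @export
per_base_depth <- function(aln, rname, ref_len, dedup = FALSE) {
  a <- aln[aln$rname == rname, , drop = FALSE]
  if (dedup) a <- a[!a$is_duplicate, , drop = FALSE]
  if (!nrow(a)) return(integer(ref_len))
  cov <- IRanges::coverage(IRanges::IRanges(start = a$start + 1L,
                                            end = a$end),
                           width = ref_len)
  as.integer(cov)
}
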