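#' Build the tail-to-head 2-LTR junction library
#'
#' For every annotated full-length copy, fuses the last `flank` bp of its 3'
#' LTR to the first `flank` bp of its 5' LTR (in element orientation;
#' minus-strand copies are reverse-complemented first). A read spanning this
#' artificial junction can only come from a circular template in which the
#' element's two ends are joined — i.e. a 2-LTR eccDNA — because the
#' genomic copy carries flanking DNA, not the other LTR, at these positions.
#' Copies whose LTRs are shorter than `flank` contribute
#' `min(flank, ltr_len)` per side.
#'
#' @param genome A `synthetic_genome`, or named character vector of
#'   chromosome sequences.
#' @param copies Truth-style data.frame of full-length copies (columns
#'   copy_id, family, chrom, start, end, strand, ltr5_start/end,
#'   ltr3_start/end); defaults to `genome$copies`.
#' @param flank Bases taken from each LTR (default 300).
#' @return data.frame of class `junction_library`: copy_id, family, seq,
#'   junction_pos (= tail_len), tail_len, head_len. Copies lacking LTR
#'   annotations are skipped with a warning.
#' @export
build_junction_library <- function(genome, copies = NULL, flank = 300) {
  chroms <- if (inherits(genome, "synthetic_genome")) genome$chromosomes
            else as_ref_vector(genome)
  if (is.null(copies)) {
    stopifnot(inherits(genome, "synthetic_genome"))
    copies <- genome$copies
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(copies))) {
    r <- copies[i, ]
    if (any(is.na(c(r$ltr5_start, r$ltr5_end, r$ltr3_start, r$ltr3_end)))) {
      skipped <- c(skipped, r$copy_id)
      next
    }
    elem <- substr0(chroms[[r$chrom]], r$start, r$end)
    if (r$strand == "-") elem <- revcomp(elem)
    l5 <- r$ltr5_end - r$ltr5_start
    l3 <- r$ltr3_end - r$ltr3_start
    tail_len <- min(flank, l3)
    head_len <- min(flank, l5)
    elen <- nchar(elem)
    seq <- paste0(substr0(elem, elen - tail_len, elen),  # 3' LTR tail
                  substr0(elem, 0, head_len))            # 5' LTR head
    rows[[length(rows) + 1L]] <- data.frame(
      copy_id = r$copy_id, family = r$family, seq = seq,
      junction_pos = tail_len, tail_len = tail_len, head_len = head_len,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " cop(ies) lacking LTR annotations: ",
            paste(head(skipped, 5), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(copy_id = character(0), family = character(0),
               seq = character(0), junction_pos = integer(0),
               tail_len = integer(0), head_len = integer(0),
               stringsAsFactors = FALSE)
  class(out) <- c("junction_library", "data.frame")
  out
}

#' Write a junction library to FASTA
#'
#' Headers encode `copy_id junction_pos=<p>`.
#' @param lib A `junction_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(lib, path) {
  write_fasta(setNames(lib$seq,
                       sprintf("%s junction_pos=%d", lib$copy_id,
                               lib$junction_pos)), path)
}

junction_refs <- function(lib) setNames(lib$seq, lib$copy_id)

#' Filter alignments to junction-spanning reads
#'
#' A read counts as junction-spanning when a single contiguous matched
#' block crosses the junction with at least `min_overlap` matched bases on
#' both LTR sides: `junction_pos - start >= min_overlap` and
#' `end - junction_pos >= min_overlap`. Blocks that merely abut the
#' junction do not count — a genuine circular template yields contiguous
#' sequence across it.
#'
#' @param aln Alignments of mobilome reads to the junction library
#'   (rname = copy_id).
#' @param lib The `junction_library` (provides junction_pos per copy).
#' @param min_overlap Minimum matched bases on each side (default 5).
#' @return The subset of `aln` that spans junctions.
#' @export
junction_spanning_reads <- function(aln, lib, min_overlap = 5) {
  if (!nrow(aln)) return(aln)
  jp <- setNames(lib$junction_pos, lib$copy_id)
  if (any(!aln$rname %in% names(jp)))
    stop("alignments reference unknown junction records")
  pos <- jp[aln$rname]
  keep <- (pos - aln$start) >= min_overlap & (aln$end - pos) >= min_overlap
  aln[keep, , drop = FALSE]
}

#' Raw junction coverage per copy
#'
#' Summed per-base depth of junction-spanning, non-duplicate reads over
#' each junction record (duplicate collapsing mirrors the
#' ignore-duplicates convention).
#'
#' @param aln Junction-spanning alignments (after
#'   [junction_spanning_reads()]).
#' @param lib The `junction_library`.
#' @param dedup Drop duplicate-flagged records (default TRUE); run
#'   [mark_duplicates()] upstream.
#' @return data.frame: copy_id, family, raw.
#' @export
junction_signal <- function(aln, lib, dedup = TRUE) {
  a <- aln
  if (dedup && nrow(a)) a <- a[!a$is_duplicate, , drop = FALSE]
  raw <- setNames(numeric(nrow(lib)), lib$copy_id)
  if (nrow(a)) {
    s <- tapply(a$end - a$start, a$rname, sum)
    raw[names(s)] <- s
  }
  data.frame(copy_id = lib$copy_id, family = lib$family,
             raw = as.numeric(raw), stringsAsFactors = FALSE)
}

#' Normalize junction coverage by sample sequencing effort
#'
#' `normalized = raw / total_genome_coverage * scale`, where
#' `total_genome_coverage` is the summed per-base depth of the same
#' sample's (organelle-filtered) reads on the reference genome. The scale
#' constant (default 1e6, i.e. per million aligned bases) only sets
#' readable magnitudes; all comparisons are ratio-based.
#'
#' @param signal Output of [junction_signal()].
#' @param total_genome_coverage Summed per-base genome depth for the
#'   sample (> 0), e.g. `sum(aln$end - aln$start)` of the genome
#'   alignments or `depth_summary(...)$total_bases`.
#' @param sample_id Sample label attached to the output.
#' @param is_genomic_control Flag carried through to the output.
#' @param scale Scaling constant (default 1e6).
#' @return data.frame: sample_id, copy_id, family, raw, normalized,
#'   is_genomic_control.
#' @export
normalize_signal <- function(signal, total_genome_coverage,
                             sample_id = "sample", is_genomic_control = FALSE,
                             scale = 1e6) {
  if (total_genome_coverage <= 0)
    stop("total genome coverage must be > 0 for normalization")
  data.frame(sample_id = sample_id, copy_id = signal$copy_id,
             family = signal$family, raw = signal$raw,
             normalized = signal$raw / total_genome_coverage * scale,
             is_genomic_control = is_genomic_control,
             stringsAsFactors = FALSE)
}

#' Aggregate per-copy mobility signals to families
#'
#' Normalized (and raw) signals are summed over the copies of each family,
#' per sample and control status.
#'
#' @param signals data.frame from [normalize_signal()] (rows may span
#'   several samples).
#' @return data.frame: sample_id, family, raw, normalized,
#'   is_genomic_control.
#' @export
family_signal <- function(signals) {
  agg <- aggregate(cbind(raw, normalized) ~ sample_id + family +
                     is_genomic_control, data = signals, FUN = sum)
  agg[order(agg$sample_id, agg$family), c("sample_id", "family", "raw",
                                          "normalized",
                                          "is_genomic_control")]
}

#' Mobility signal of one sample against a junction library
#'
#' Runs the full per-sample junction recipe: all-hits alignment of the
#' reads to the junction library, junction-spanning filter, duplicate
#' marking, raw coverage, and normalization by the sample's total genome
#' coverage (from a best-hit alignment of the same reads to the reference).
#'
#' @param reads A `read_set` (organelle-filtered mobilome or WGS reads).
#' @param lib A `junction_library`.
#' @param genome Reference genome (for the normalizer).
#' @param sample_id Sample label.
#' @param min_overlap Junction overlap rule (default 5 bp).
#' @param is_genomic_control Set TRUE when `reads` are genomic (WGS) reads;
#'   see [genomic_control()].
#' @param ... Passed to [naive_align()].
#' @return Per-copy signal data.frame (see [normalize_signal()]).
#' @export
mobility_signal <- function(reads, lib, genome, sample_id = "sample",
                            min_overlap = 5, is_genomic_control = FALSE,
                            ...) {
  refs <- as_ref_vector(genome)
  if (!nrow(reads)) {
    warning("empty read set: zero signal for all copies")
    return(data.frame(sample_id = sample_id, copy_id = lib$copy_id,
                      family = lib$family, raw = 0, normalized = 0,
                      is_genomic_control = is_genomic_control,
                      stringsAsFactors = FALSE))
  }
  aln_j <- naive_align(reads, junction_refs(lib), all_hits = TRUE, ...)
  aln_j <- mark_duplicates(junction_spanning_reads(aln_j, lib, min_overlap))
  sig <- junction_signal(aln_j, lib, dedup = TRUE)
  aln_g <- naive_align(reads, refs, all_hits = FALSE, ...)
  total <- sum(aln_g$end - aln_g$start)
  normalize_signal(sig, total, sample_id = sample_id,
                   is_genomic_control = is_genomic_control)
}

#' Genomic-read background control for junction signals
#'
#' Applies the identical junction computation to genomic (WGS) reads of
#' the same genotype; reported side-by-side with mobilome signals, the
#' mobilome-specific evidence is signal in excess of this background
#' (undigested linear DNA can contain inserted LTR-LTR junction look-alike
#' sequence, e.g. at tandem or nested insertions).
#'
#' @param wgs_reads A `read_set` of genomic reads.
#' @inheritParams mobility_signal
#' @return Per-copy signal data.frame flagged `is_genomic_control = TRUE`.
#' @export
genomic_control <- function(wgs_reads, lib, genome, sample_id = "genomic",
                            min_overlap = 5, ...) {
  mobility_signal(wgs_reads, lib, genome, sample_id = sample_id,
                  min_overlap = min_overlap, is_genomic_control = TRUE, ...)
}
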