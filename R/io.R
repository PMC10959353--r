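#' Write sequences to FASTA
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a read set to FASTQ (Phred+33, constant quality)
#' @param reads A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(q, path)
  invisible(path)
}

#' Read a FASTQ file as a read set
#' @param path FASTQ path.
#' @return A `read_set` data.frame (read_id, seq).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  new_read_set(sub("\\s.*$", "", names(x)), as.character(x), truth = NULL)
}

#' Downsample read sets to a common size
#'
#' All sets are reduced to the read count of the smallest set by uniform
#' sampling without replacement, so per-sample coverage statistics become
#' comparable across samples.
#'
#' @param readsets List of `read_set` objects.
#' @param seed Integer seed.
#' @return List of downsampled `read_set` objects, in input order.
#' @export
downsample <- function(readsets, seed = 1) {
  if (!length(readsets)) stop("need at least one read set")
  counts <- vapply(readsets, nrow, integer(1))
  if (any(counts == 0)) stop("empty read set cannot be downsampled")
  n_min <- min(counts)
  with_seed(derive_seed(seed, "downsample"), {
    lapply(readsets, function(rs) {
      if (nrow(rs) == n_min) return(rs)
      keep <- sort(sample.int(nrow(rs), n_min))
      out <- rs[keep, , drop = FALSE]
      tr <- attr(rs, "truth")
      if (!is.null(tr)) tr <- tr[tr$read_id %in% out$read_id, , drop = FALSE]
      new_read_set(out$read_id, out$seq, tr, attr(rs, "paired"))
    })
  })
}

#' Remove reads of organelle origin
#'
#' Aligns reads against organelle reference sequences (e.g. the chloroplast
#' genome) and retains only reads with no acceptable alignment, mirroring
#' the keep-unmapped convention (`samtools view -f 4`) used to clean
#' mobilome libraries dominated by organelle circles.
#'
#' @param reads A `read_set`.
#' @param organelle_refs Named character vector / DNAStringSet / FASTA path.
#' @param seed_len Aligner seed length.
#' @return The retained `read_set`.
#' @export
filter_organelle <- function(reads, organelle_refs, seed_len = 31) {
  refs <- as_ref_vector(organelle_refs)
  if (!length(refs) || all(nchar(refs) == 0))
    stop("organelle references must be non-empty")
  if (nrow(reads) == 0) return(reads)
  aln <- naive_align(reads, refs, seed_len = seed_len, all_hits = FALSE)
  keep <- !(reads$read_id %in% aln$read_id)
  out <- reads[keep, , drop = FALSE]
  tr <- attr(reads, "truth")
  if (!is.null(tr)) tr <- tr[tr$read_id %in% out$read_id, , drop = FALSE]
  new_read_set(out$read_id, out$seq, tr, attr(reads, "paired"))
}

as_ref_vector <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && is.null(names(reference)))
    return(read_fasta(reference))
  if (is(reference, "DNAStringSet"))
    return(setNames(as.character(reference), names(reference)))
  if (inherits(reference, "synthetic_genome"))
    return(reference$chromosomes)
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- sprintf("ref%d", seq_along(reference))
    return(reference)
  }
  stop("unsupported reference type")
}

#' Write alignments to a SAM file
#'
#' Minimal headerful SAM: `@SQ` lines from the reference lengths, one line
#' per alignment record, CIGAR of the form `xSyMzS`, NM tag with the
#' mismatch count. Secondary records (beyond the first per read) carry flag
#' 0x100, duplicates 0x400.
#'
#' @param aln Alignment data.frame from [naive_align()].
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                       as.integer(ref_lengths))), con)
  if (nrow(aln)) {
    secondary <- duplicated(aln$read_id)
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(secondary, 256L, 0L) +
      ifelse(isTRUE_vec(aln$is_duplicate), 1024L, 0L)
    span <- aln$end - aln$start
    cigar <- paste0(ifelse(aln$clip_left > 0,
                           paste0(aln$clip_left, "S"), ""),
                    span, "M",
                    ifelse(aln$clip_right > 0,
                           paste0(aln$clip_right, "S"), ""))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                       aln$read_id, flag, aln$rname, aln$start + 1L,
                       aln$mapq, cigar, aln$nm), con)
  }
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Read a SAM file into an alignment data.frame
#'
#' Parses the subset of SAM consumed by the pipeline (coordinates, strand,
#' soft clips, duplicate/secondary flags, NM). Split alignments encoded
#' with `N` in the CIGAR yield one row per matched block. Coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path SAM path.
#' @return Alignment data.frame with the [naive_align()] columns.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || f[3] == "*") next
    pos <- as.integer(f[4]) - 1L
    ops <- cigar_ops(f[6])
    nm <- 0L
    nm_f <- grep("^NM:i:", f, value = TRUE)
    if (length(nm_f)) nm <- as.integer(sub("NM:i:", "", nm_f[1]))
    clip_left <- if (nrow(ops) && ops$op[1] %in% c("S", "H"))
      ops$len[1] else 0L
    clip_right <- if (nrow(ops) && ops$op[nrow(ops)] %in% c("S", "H"))
      ops$len[nrow(ops)] else 0L
    # walk ref-consuming ops; N splits blocks
    blocks <- list(); bstart <- pos; cur <- pos
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op %in% c("M", "=", "X", "D")) cur <- cur + len
      else if (op == "N") {
        blocks[[length(blocks) + 1L]] <- c(bstart, cur)
        cur <- cur + len; bstart <- cur
      }
    }
    blocks[[length(blocks) + 1L]] <- c(bstart, cur)
    for (b in blocks) {
      if (b[2] <= b[1]) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = f[1], rname = f[3], start = b[1], end = b[2],
        strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
        nm = nm, clip_left = clip_left, clip_right = clip_right,
        n_clipped = clip_left + clip_right,
        mapq = as.integer(f[5]),
        is_duplicate = bitwAnd(flag, 1024L) > 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_alignments())
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

cigar_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}
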