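#' Select the longest contigs of a mobilome assembly
#'
#' Rolling-circle amplification gives mobile elements very high coverage,
#' so the longest assembled contigs are the best full-length eccDNA
#' candidates. Ranks by sequence length, ties broken by input order
#' (stable), and returns at most `n` contigs.
#'
#' @param contigs data.frame with contig_id and seq (e.g. [make_contigs()]
#'   output), or a named character vector of sequences.
#' @param n Number of contigs to keep (default 10).
#' @return The selected rows / elements, longest first.
#' @export
top_contigs <- function(contigs, n = 10) {
  if (is.character(contigs)) {
    lens <- nchar(contigs)
    return(contigs[order(-lens)][seq_len(min(n, length(contigs)))])
  }
  lens <- if ("length" %in% names(contigs)) contigs$length
          else nchar(contigs$seq)
  contigs[order(-lens)[seq_len(min(n, nrow(contigs)))], , drop = FALSE]
}

#' Convert contig alignments to labeled genomic intervals
#'
#' Each matched block of a (possibly split) contig alignment becomes one
#' interval labeled with its contig and sample of origin, the bamtobed
#' `-split` convention. Unmapped contigs contribute nothing (reported via
#' a message).
#'
#' @param aln Alignments of contigs to the reference (one row per block;
#'   read_id = contig_id).
#' @param contig_samples Named character vector contig_id -> sample_id.
#' @return data.frame: chrom, start, end, contig_id, sample_id.
#' @export
contig_regions <- function(aln, contig_samples) {
  unmapped <- setdiff(names(contig_samples), unique(aln$read_id))
  if (length(unmapped))
    message(length(unmapped), " contig(s) unmapped: ",
            paste(head(unmapped, 5), collapse = ", "))
  if (!nrow(aln))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), contig_id = character(0),
                      sample_id = character(0), stringsAsFactors = FALSE))
  if (any(!aln$read_id %in% names(contig_samples)))
    stop("alignment contains contigs without a sample label")
  data.frame(chrom = aln$rname, start = aln$start, end = aln$end,
             contig_id = aln$read_id,
             sample_id = unname(contig_samples[aln$read_id]),
             stringsAsFactors = FALSE)
}

#' Merge overlapping contig intervals into circle-forming regions
#'
#' Overlapping or book-ended intervals are merged (the bedtools merge
#' default); per region the distinct contigs, distinct samples and the
#' interval count are recorded.
#'
#' @param intervals data.frame from [contig_regions()].
#' @return data.frame of class `circle_regions`: chrom, start, end
#'   (0-based half-open), n_intervals, n_contigs, n_samples, contig_ids,
#'   samples (";"-separated).
#' @export
merge_regions <- function(intervals) {
  if (!nrow(intervals))
    return(empty_regions())
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- lapply(seq_along(red), function(i) {
    idx <- revmap[[i]]
    contigs <- unique(intervals$contig_id[idx])
    samples <- unique(intervals$sample_id[idx])
    data.frame(chrom = as.character(GenomicRanges::seqnames(red))[i],
               start = GenomicRanges::start(red)[i] - 1L,
               end = GenomicRanges::end(red)[i],
               n_intervals = length(idx), n_contigs = length(contigs),
               n_samples = length(samples),
               contig_ids = paste(sort(contigs), collapse = ";"),
               samples = paste(sort(samples), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("circle_regions", "data.frame")
  out
}

empty_regions <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_intervals = integer(0),
                    n_contigs = integer(0), n_samples = integer(0),
                    contig_ids = character(0), samples = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("circle_regions", "data.frame")
  out
}

#' Retain regions supported by enough samples
#'
#' Circle-forming regions occurring in fewer than `min_samples` distinct
#' samples are discarded as irreproducible.
#'
#' @param regions A `circle_regions` data.frame.
#' @param min_samples Minimum distinct samples (default 3).
#' @return The retained regions.
#' @export
retain_regions <- function(regions, min_samples = 3) {
  regions[regions$n_samples >= min_samples, , drop = FALSE]
}

#' Classify regions by stress/genotype specificity or recurrence
#'
#' For each region, contigs are attributed to the category (stress or
#' genotype) of their sample of origin. `specificity` is the fraction of
#' contigs from the modal category; a region is `SPECIFIC` when that
#' fraction exceeds 0.5 (strict majority), otherwise `RECURRENT` when it
#' occurs in at least `min_recurrent_samples` samples, else `NONE`. On a
#' modal tie there is no majority, so the call falls through to
#' RECURRENT/NONE with the tied maximum reported as specificity.
#'
#' @param regions A `circle_regions` data.frame.
#' @param sample_labels Named vector sample_id -> category for the chosen
#'   axis.
#' @param axis Label for the axis ("stress" or "genotype").
#' @param min_recurrent_samples Sample count for the RECURRENT call
#'   (default 10).
#' @param contig_samples Optional named vector contig_id -> sample_id;
#'   defaults to parsing the `"sample|contig"` naming used by the
#'   pipeline helpers.
#' @return data.frame: region columns plus axis, top_category,
#'   specificity, klass.
#' @export
specificity <- function(regions, sample_labels, axis = "genotype",
                        min_recurrent_samples = 10, contig_samples = NULL) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    contigs <- strsplit(r$contig_ids, ";", fixed = TRUE)[[1]]
    samples <- if (!is.null(contig_samples))
      unname(contig_samples[contigs]) else contig_sample_of(contigs)
    unlabeled <- setdiff(samples, names(sample_labels))
    if (length(unlabeled))
      stop("no ", axis, " label for sample(s): ",
           paste(unique(unlabeled), collapse = ", "))
    cats <- table(sample_labels[samples])
    spec <- max(cats) / length(contigs)
    tied <- sum(cats == max(cats)) > 1
    klass <- if (!tied && spec > 0.5) "SPECIFIC"
             else if (r$n_samples >= min_recurrent_samples) "RECURRENT"
             else "NONE"
    data.frame(r, axis = axis,
               top_category = names(cats)[which.max(cats)],
               specificity = spec, klass = klass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pipeline helpers name contigs "<sample>|<contig>"
contig_sample_of <- function(contig_ids) {
  vapply(strsplit(contig_ids, "|", fixed = TRUE), `[[`, character(1), 1)
}

#' Annotate circle-forming regions with overlapping features
#'
#' Overlapping gene and TE feature names are concatenated (";") per
#' region. Region sequences of at least `min_seq_len` bp are extracted
#' from the genome (candidates long enough to represent full-length mobile
#' LTR-RTs); shorter regions are flagged `below_length`.
#'
#' @param regions A `circle_regions` data.frame.
#' @param genes GRanges of genes, a GFF3 path, or NULL. Feature names are
#'   taken from `Name`, `ID` or names().
#' @param tes data.frame of TE copies (chrom/start/end 0-based half-open
#'   with family or copy_id), GRanges, or NULL.
#' @param genome `synthetic_genome` or named chromosome vector (for
#'   sequence extraction); NULL to skip extraction.
#' @param min_seq_len Minimum extracted length (default 2000).
#' @return Regions with `annotations`, `seq_len`, `below_length` columns;
#'   extracted sequences in `attr(, "sequences")`.
#' @export
annotate_regions <- function(regions, genes = NULL, tes = NULL,
                             genome = NULL, min_seq_len = 2000) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  ann <- rep("", nrow(regions))
  add_overlaps <- function(ann, feat_gr, feat_names) {
    hits <- GenomicRanges::findOverlaps(gr, feat_gr)
    for (i in unique(S4Vectors::queryHits(hits))) {
      nm <- feat_names[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      ann[i] <- paste(c(if (nzchar(ann[i])) ann[i], unique(nm)),
                      collapse = ";")
    }
    ann
  }
  if (!is.null(genes)) {
    if (is.character(genes)) {
      genes <- rtracklayer::import(genes)
      genes <- genes[genes$type == "gene"]
    }
    nms <- if (!is.null(genes$Name)) genes$Name
           else if (!is.null(genes$ID)) genes$ID
           else if (!is.null(names(genes))) names(genes)
           else sprintf("gene%d", seq_along(genes))
    ann <- add_overlaps(ann, genes, nms)
  }
  if (!is.null(tes)) {
    if (is.data.frame(tes)) {
      te_gr <- GenomicRanges::GRanges(tes$chrom,
                                      IRanges::IRanges(tes$start + 1L,
                                                       tes$end))
      te_names <- if ("family" %in% names(tes)) tes$family else tes$copy_id
    } else {
      te_gr <- tes
      te_names <- if (!is.null(names(tes))) names(tes)
                  else sprintf("TE%d", seq_along(tes))
    }
    ann <- add_overlaps(ann, te_gr, te_names)
  }
  regions$annotations <- ann
  regions$seq_len <- regions$end - regions$start
  regions$below_length <- regions$seq_len < min_seq_len
  seqs <- NULL
  if (!is.null(genome)) {
    chroms <- if (inherits(genome, "synthetic_genome")) genome$chromosomes
              else as_ref_vector(genome)
    missing_chrom <- setdiff(unique(regions$chrom), names(chroms))
    if (length(missing_chrom))
      stop("chromosome(s) missing from genome: ",
           paste(missing_chrom, collapse = ", "))
    keep <- !regions$below_length
    seqs <- setNames(
      mapply(function(ch, s, e) substr0(chroms[[ch]], s, e),
             regions$chrom[keep], regions$start[keep], regions$end[keep]),
      sprintf("%s:%d-%d", regions$chrom[keep], regions$start[keep],
              regions$end[keep]))
  }
  attr(regions, "sequences") <- seqs
  regions
}
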