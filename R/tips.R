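#' Filter TIP calls shared across genetic backgrounds
#'
#' A candidate transposon insertion polymorphism (TIP) detected at the same
#' site in multiple individuals from more than one genetic background
#' cannot be a recent de novo insertion of the focal line — it is standing
#' variation (or a systematic artifact) and is removed. Calls are clustered
#' per (chromosome, family) by single-linkage with a positional tolerance
#' that absorbs TSD-induced breakpoint ambiguity.
#'
#' @param calls data.frame with columns sample_id, background, chrom, pos,
#'   family (extra columns are carried through).
#' @param site_tolerance Maximum distance (bp) linking two calls into one
#'   site (default 10).
#' @return The retained calls (clusters confined to one individual or one
#'   background).
#' @export
filter_shared_tips <- function(calls, site_tolerance = 10) {
  if (!nrow(calls)) return(calls)
  if (any(is.na(calls$background) | !nzchar(calls$background)))
    stop("every call needs a background label")
  calls$.cluster <- NA_integer_
  cl <- 0L
  for (key in unique(paste(calls$chrom, calls$family, sep = "\r"))) {
    idx <- which(paste(calls$chrom, calls$family, sep = "\r") == key)
    idx <- idx[order(calls$pos[idx])]
    pos <- calls$pos[idx]
    new_cluster <- c(TRUE, diff(pos) > site_tolerance)
    calls$.cluster[idx] <- cl + cumsum(new_cluster)
    cl <- cl + sum(new_cluster)
  }
  drop_cluster <- vapply(split(seq_len(nrow(calls)), calls$.cluster),
                         function(i) {
    length(unique(calls$sample_id[i])) >= 2 &&
      length(unique(calls$background[i])) >= 2
  }, logical(1))
  keep <- !drop_cluster[as.character(calls$.cluster)]
  out <- calls[keep, setdiff(names(calls), ".cluster"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clipped-read fraction at an insertion site
#'
#' Among reads overlapping the insertion point, counts reads soft-clipped
#' at the point (their matched block ends within `tol` bp of it, evidence
#' the read continues into inserted sequence absent from the reference)
#' versus reads spanning the point without clipping (evidence of a
#' haplotype lacking the insertion). The fraction
#' `n_clipped / (n_clipped + n_spanning)` is ~1 for homozygous insertions,
#' ~0.5 for heterozygous ones, and markedly lower for insertions carried
#' by only a fraction of cells (somatic).
#'
#' @param aln Alignments to the reference around the site.
#' @param chrom Chromosome of the insertion.
#' @param pos Insertion point (0-based, between `pos-1` and `pos`).
#' @param tol Clip-position tolerance in bp (default 10; absorbs TSDs).
#' @return list(n_clipped, n_spanning, fraction); fraction is NA when no
#'   read overlaps the point.
#' @export
clipped_fraction <- function(aln, chrom, pos, tol = 10) {
  a <- aln[aln$rname == chrom, , drop = FALSE]
  clipped_at <- (a$clip_right > 0 & abs(a$end - pos) <= tol) |
    (a$clip_left > 0 & abs(a$start - pos) <= tol)
  spanning <- a$start < pos & a$end > pos & !clipped_at
  n_clipped <- sum(clipped_at)
  n_spanning <- sum(spanning)
  fraction <- if (n_clipped + n_spanning == 0) {
    message("no reads overlap the insertion point; fraction is missing")
    NA_real_
  } else n_clipped / (n_clipped + n_spanning)
  list(n_clipped = n_clipped, n_spanning = n_spanning, fraction = fraction)
}

#' Zygosity hint from a clipped-read fraction
#'
#' Band convention: fraction < 0.35 -> "somatic-like" (too few clipped
#' reads for a germline insertion), 0.35–0.85 -> "heterozygous-like",
#' > 0.85 -> "homozygous-like"; calls with fewer than `min_support` split
#' reads are "support-poor". The heterozygous band is asymmetric because a
#' full-length insertion sheds clipped reads from both of its junctions
#' (which project to the same reference point) while the insertion-free
#' haplotype contributes spanning reads once, centering heterozygous sites
#' slightly above 0.5. The bands are reporting conventions to guide
#' curation, not calibrated genotype calls.
#'
#' @param fraction Clipped-read fraction.
#' @param n_split_support Split-read support count of the call.
#' @param min_support Minimum split support (default 2).
#' @return Character hint.
#' @export
zygosity_hint <- function(fraction, n_split_support = Inf, min_support = 2) {
  hint <- function(f, s) {
    if (s < min_support) return("support-poor")
    if (is.na(f)) return("no-coverage")
    if (f < 0.35) "somatic-like"
    else if (f <= 0.85) "heterozygous-like"
    else "homozygous-like"
  }
  mapply(hint, fraction, n_split_support, USE.NAMES = FALSE)
}
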