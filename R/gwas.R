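#' Filter GWAS sites on allele frequency and missingness
#'
#' Keeps SNPs with minor-allele frequency at least `maf_min` and
#' missingness at most `miss_max` (boundary inclusive on both: "more than
#' 5% missing" is excluded).
#'
#' @param snps data.frame with columns maf and missingness (others carried
#'   through).
#' @param maf_min MAF threshold (default 0.05).
#' @param miss_max Missingness threshold (default 0.05).
#' @return Filtered data.frame.
#' @export
site_filters <- function(snps, maf_min = 0.05, miss_max = 0.05) {
  snps[snps$maf >= maf_min & snps$missingness <= miss_max, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity (delegates to
#' [stats::p.adjust()]); input must lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bonferroni significance threshold
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Candidate windows around significant GWAS SNPs
#'
#' Slides fixed-size windows anchored at multiples of `step` from position
#' 0 on each chromosome and keeps every window `[start, start + window)`
#' containing at least `min_snps` significant SNPs. Anchoring at 0 makes
#' window coordinates reproducible across runs and families.
#'
#' @param snps data.frame with chrom, pos and logical significant.
#' @param window Window size in bp (default 20000).
#' @param step Anchor spacing in bp (default 10000, i.e. 50% overlap).
#' @param min_snps Minimum significant SNPs per window (default 2).
#' @return data.frame: chrom, start, end, n_significant_snps.
#' @export
candidate_windows <- function(snps, window = 20000, step = 10000,
                              min_snps = 2) {
  sig <- snps[snps$significant %in% TRUE, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    pos <- sort(sig$pos[sig$chrom == ch])
    anchors <- seq(0, max(pos), by = step)
    for (a in anchors) {
      n <- sum(pos >= a & pos < a + window)
      if (n >= min_snps)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = a, end = a + window,
          n_significant_snps = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_significant_snps = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Genes overlapping candidate windows, with UpSet-style intersections
#'
#' A gene belongs to a family's candidate set when its span overlaps any
#' of that family's kept windows by at least 1 bp. Exclusive intersection
#' counts (the cells of an UpSet plot) are computed across the per-family
#' gene sets.
#'
#' @param windows data.frame of candidate windows with a `family` column
#'   (chrom, start, end 0-based half-open).
#' @param genes GRanges of genes, a GFF3 path, or a data.frame with chrom,
#'   start, end (0-based half-open) and gene_id.
#' @return list with `gene_sets` (named list of gene-id vectors per
#'   family) and `intersections` (data.frame: combination, n_genes).
#' @export
genes_in_windows <- function(windows, genes) {
  gene_df <- normalize_genes(genes)
  fams <- unique(windows$family)
  gene_sets <- lapply(setNames(fams, fams), function(f) {
    w <- windows[windows$family == f, , drop = FALSE]
    hit <- logical(nrow(gene_df))
    for (i in seq_len(nrow(w))) {
      hit <- hit | (gene_df$chrom == w$chrom[i] &
                      gene_df$start < w$end[i] & gene_df$end > w$start[i])
    }
    gene_df$gene_id[hit]
  })
  all_genes <- unique(unlist(gene_sets))
  if (!length(all_genes)) {
    return(list(gene_sets = gene_sets,
                intersections = data.frame(combination = character(0),
                                           n_genes = integer(0),
                                           stringsAsFactors = FALSE)))
  }
  membership <- vapply(gene_sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(gene_sets)))
  combo <- apply(membership, 1, function(m)
    paste(colnames(membership)[m], collapse = "&"))
  tab <- table(combo)
  list(gene_sets = gene_sets,
       intersections = data.frame(combination = names(tab),
                                  n_genes = as.integer(tab),
                                  stringsAsFactors = FALSE))
}

normalize_genes <- function(genes) {
  if (is.character(genes)) {
    genes <- rtracklayer::import(genes)
    genes <- genes[genes$type == "gene"]
  }
  if (is(genes, "GRanges")) {
    ids <- if (!is.null(genes$ID)) genes$ID
           else if (!is.null(genes$Name)) genes$Name
           else sprintf("gene%d", seq_along(genes))
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                      start = GenomicRanges::start(genes) - 1L,
                      end = GenomicRanges::end(genes),
                      gene_id = ids, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  genes
}

#' Flag SNPs within a linkage distance of features
#'
#' Supports the "linked (+/- d bp)" annotation convention: a SNP is linked
#' to a feature when it lies within `dist` bp of the feature span.
#'
#' @param snps data.frame with chrom, pos.
#' @param features data.frame with chrom, start, end (0-based half-open).
#' @param dist Linkage distance in bp (default 10000).
#' @return Logical vector, one element per SNP.
#' @export
snps_near_features <- function(snps, features, dist = 10000) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(features$chrom == snps$chrom[i] &
          snps$pos[i] >= features$start - dist &
          snps$pos[i] < features$end + dist)
  }, logical(1))
}
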