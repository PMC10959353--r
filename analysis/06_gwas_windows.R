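#!/usr/bin/env Rscript
# GWAS post-processing: site filters, FDR/Bonferroni thresholds, 20 kb/10 kb
# candidate windows, overlapping genes and cross-family intersections, on a
# simulated per-SNP p-value table with planted association peaks.

library(mobiloscope)

out <- "results"
dir.create(out, showWarnings = FALSE)
set.seed(61)

## simulate two families' GWAS tables with a shared and a private peak --------
n_snp <- 20000
mk_snps <- function(peaks) {
  snps <- data.frame(chrom = "chr1",
                     pos = sort(sample.int(5e6, n_snp)),
                     maf = runif(n_snp, 0, 0.5),
                     missingness = runif(n_snp, 0, 0.2))
  snps$p_value <- runif(n_snp)
  for (p in peaks) {
    hit <- abs(snps$pos - p) < 15000
    snps$p_value[hit] <- snps$p_value[hit] * 1e-8
  }
  snps
}
tables <- list(famA = mk_snps(c(1.2e6, 3.4e6)), famB = mk_snps(3.4e6))

windows <- list()
for (f in names(tables)) {
  snps <- site_filters(tables[[f]])
  snps$significant <- bh_fdr(snps$p_value) < 0.05
  bonf <- snps$p_value < bonferroni_threshold(nrow(snps))
  cat(sprintf("%s: %d/%d SNPs pass site filters; %d FDR-significant, %d Bonferroni\n",
              f, nrow(snps), n_snp, sum(snps$significant), sum(bonf)))
  w <- candidate_windows(snps, window = 20000, step = 10000, min_snps = 2)
  w$family <- f
  windows[[f]] <- w
}
win <- do.call(rbind, windows)
write.table(win, file.path(out, "candidate_windows.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

## genes overlapping windows, UpSet-style intersections -----------------------
gene_start <- seq(10000, 4.99e6, by = 25000)
genes <- data.frame(chrom = "chr1", start = gene_start,
                    end = gene_start + 4000,
                    gene_id = sprintf("gene%04d", seq_along(gene_start)),
                    stringsAsFactors = FALSE)
res <- genes_in_windows(win, genes)
for (f in names(res$gene_sets))
  write.table(data.frame(gene_id = res$gene_sets[[f]]),
              file.path(out, sprintf("genes_%s.tsv", f)), sep = "\t",
              quote = FALSE, row.names = FALSE)
write.table(res$intersections, file.path(out, "gene_intersections.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("candidate windows: %s\n",
            paste(sprintf("%s=%d", names(windows),
                          vapply(windows, nrow, integer(1))),
                  collapse = ", ")))
cat("gene-set intersections (UpSet cells):\n")
print(res$intersections, row.names = FALSE)
cat("-> the shared peak at 3.4 Mb concentrates genes in the famA&famB cell\n")
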