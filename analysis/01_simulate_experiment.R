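#!/usr/bin/env Rscript
# Simulate the full mobilome study: LTR-RT families, a genome carrying
# full-length copies with TSDs, 12 mobilome samples (2 genotypes x 2
# stresses) with eccDNA pools and rolling-circle reads. Writes the
# reference inputs other drivers re-derive (deterministically) and a
# summary of what was generated.

library(mobiloscope)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

ex <- simulate_mobilome_experiment(seed = seed)

write_family_fasta(ex$families, file.path(out, "families.fa"))
write_fasta(ex$genome$chromosomes, file.path(out, "genome.fa"))
write_truth_bed(ex$genome, file.path(out, "copies.bed"))
write_truth_gff3(ex$genome, file.path(out, "copies.gff3"))
write.table(ex$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

circ <- do.call(rbind, lapply(names(ex$pools), function(s)
  cbind(sample_id = s, eccdna_truth(ex$pools[[s]]))))
write.table(circ, file.path(out, "circles_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d bp, %d full-length copies (%d families)\n",
            genome_length(ex$genome), nrow(ex$genome$copies),
            length(ex$families)))
cat(sprintf("samples: %d (%s)\n", nrow(ex$samples),
            paste(sprintf("%s=%d", names(table(ex$samples$genotype)),
                          table(ex$samples$genotype)), collapse = ", ")))
cat(sprintf("circles: %s\n",
            paste(sprintf("%s=%d", names(table(circ$kind)),
                          table(circ$kind)), collapse = ", ")))
cat(sprintf("reads: %d total across samples\n",
            sum(vapply(ex$reads, nrow, integer(1)))))
cat(sprintf("active family (2-LTR circles, mutant only): %s\n",
            ex$active_family))
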