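# Small shared fixtures, built once per test run.

fix_env <- new.env()

# two dissimilar families with 300 bp LTRs, 2 kb internal
small_families <- function() {
  if (is.null(fix_env$fams))
    fix_env$fams <- make_family_panel(2, ltr_len = 300, internal_len = 2000,
                                      seed = 101)
  fix_env$fams
}

# 100 kb genome with 2 copies of each small family
small_genome <- function() {
  if (is.null(fix_env$genome)) {
    fams <- small_families()
    fix_env$genome <- build_genome(
      fams, setNames(c(2L, 2L), names(fams)), chrom_len = 100000,
      seed = 102)
  }
  fix_env$genome
}

# TE-free 100 kb genome (exact length, for read-count arithmetic)
plain_genome <- function() {
  if (is.null(fix_env$plain)) {
    fams <- small_families()
    fix_env$plain <- build_genome(fams, setNames(c(0L, 0L), names(fams)),
                                  chrom_len = 100000, seed = 103)
  }
  fix_env$plain
}

# hand-built alignment row(s) for unit tests of coverage/junction filters
aln_row <- function(read_id = "r1", rname = "ref", start = 0L, end = 100L,
                    strand = "+", nm = 0L, clip_left = 0L, clip_right = 0L,
                    mapq = 60L, is_duplicate = FALSE) {
  data.frame(read_id = read_id, rname = rname, start = start, end = end,
             strand = strand, nm = nm, clip_left = clip_left,
             clip_right = clip_right, n_clipped = clip_left + clip_right,
             mapq = mapq, is_duplicate = is_duplicate,
             stringsAsFactors = FALSE)
}

empty_alignments_df <- function() mobiloscope:::empty_alignments()

# random interval sets for merge/window property tests
random_intervals <- function(n, max_pos = 1000, max_len = 50,
                             samples = sprintf("s%d", 1:6)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             contig_id = sprintf("c%d", seq_len(n)),
             sample_id = sample(samples, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
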