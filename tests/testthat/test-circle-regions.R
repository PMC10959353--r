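test_that("top contig selection ranks by length with stable ties", {
  set.seed(1)
  lens <- c(sample(101:200, 12), 100, 100, 50)
  contigs <- data.frame(contig_id = sprintf("c%02d", seq_along(lens)),
                        seq = vapply(lens, function(n) strrep("A", n),
                                     character(1)),
                        stringsAsFactors = FALSE)
  top <- top_contigs(contigs, n = 10)
  expect_equal(nrow(top), 10)
  expect_equal(sort(nchar(top$seq), decreasing = TRUE), nchar(top$seq))
  expect_true(all(nchar(top$seq) >= sort(lens, decreasing = TRUE)[10]))
  # fewer than n: all returned
  expect_equal(nrow(top_contigs(contigs[1:3, ], n = 10)), 3)
  # tie at the cut: first-encountered kept, deterministic
  tie <- data.frame(contig_id = c("first", "second"),
                    seq = c(strrep("A", 100), strrep("C", 100)),
                    stringsAsFactors = FALSE)
  expect_equal(top_contigs(tie, n = 1)$contig_id, "first")
})

test_that("contig alignments become split-aware labeled intervals", {
  g <- small_genome()
  chrom <- g$chromosomes[[1]]
  # a chimeric contig from two distant genome segments -> 2 intervals
  contig <- paste0(substr(chrom, 5001, 5400), substr(chrom, 40001, 40300))
  aln <- naive_align(c(`s1|chimera` = contig), g, max_mm_per100 = 0)
  iv <- contig_regions(aln, c(`s1|chimera` = "s1"))
  expect_equal(nrow(iv), 2)
  iv <- iv[order(iv$start), ]
  # breakpoint edges may gain a couple of chance-matching bases
  expect_lte(max(abs(iv$start - c(5000, 40000))), 3)
  expect_lte(max(abs(iv$end - c(5400, 40300))), 3)
  # an ungapped contig -> a single interval matching its span
  simple <- substr(chrom, 7001, 7600)
  iv2 <- contig_regions(naive_align(c(`s1|simple` = simple), g,
                                    max_mm_per100 = 0),
                        c(`s1|simple` = "s1"))
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$start, 7000)
  expect_equal(iv2$end, 7600)
  # a contig built from a truth eccDNA fragment maps back exactly
  cid <- g$copies$copy_id[1]
  pool <- simulate_eccdna_pool(g, c(FRAGMENT = 1), copies = cid, seed = 3)
  contig3 <- make_contigs(pool, rotate = FALSE, seed = 4)
  aln3 <- naive_align(setNames(contig3$seq, "s2|frag"), g,
                      max_mm_per100 = 0)
  iv3 <- contig_regions(aln3, c(`s2|frag` = "s2"))
  hitpos <- gregexpr(contig3$seq[1], chrom, fixed = TRUE)[[1]][1]
  if (hitpos < 0)   # minus-strand copy: fragment is reverse-complemented
    hitpos <- gregexpr(revcomp(contig3$seq[1]), chrom, fixed = TRUE)[[1]][1]
  elem_sub <- hitpos - 1
  expect_true(any(iv3$start == elem_sub &
                    iv3$end == elem_sub + nchar(contig3$seq[1])))
  # unmapped contigs are reported, not silently dropped
  expect_message(
    contig_regions(empty_alignments_df(), c(x = "s1")), "unmapped")
})

test_that("region merging matches bedtools semantics", {
  iv <- data.frame(chrom = "chr1", start = c(1, 50), end = c(100, 150),
                   contig_id = c("c1", "c2"), sample_id = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  m <- merge_regions(iv)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1); expect_equal(m$end, 150)
  expect_equal(m$n_contigs, 2); expect_equal(m$n_samples, 2)
  expect_setequal(strsplit(m$samples, ";")[[1]], c("s1", "s2"))
  # disjoint intervals stay separate; book-ended intervals merge
  iv2 <- data.frame(chrom = "chr1", start = c(1, 200, 300),
                    end = c(100, 300, 400),
                    contig_id = c("a", "b", "c"), sample_id = "s1",
                    stringsAsFactors = FALSE)
  m2 <- merge_regions(iv2)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$end[2], 400)
})

test_that("merge is idempotent and conserves totals on random sets", {
  set.seed(11)
  for (rep in 1:1000) {
    iv <- random_intervals(sample(2:12, 1))
    m <- merge_regions(iv)
    # output disjoint and sorted per chromosome
    for (ch in unique(m$chrom)) {
      mm <- m[m$chrom == ch, ]
      if (nrow(mm) > 1) {
        expect_true(all(diff(mm$start) > 0))
        expect_true(all(mm$start[-1] > mm$end[-nrow(mm)]))
      }
    }
    expect_equal(sum(m$n_intervals), nrow(iv))
    # merging the merged output changes nothing
    as_iv <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                        contig_id = sprintf("m%d", seq_len(nrow(m))),
                        sample_id = "s", stringsAsFactors = FALSE)
    m2 <- merge_regions(as_iv)
    expect_equal(m2[, c("chrom", "start", "end")],
                 m[, c("chrom", "start", "end")], ignore_attr = TRUE)
  }
})

test_that("retention threshold equals a brute-force filter", {
  mk_region <- function(samples) {
    data.frame(chrom = "chr1", start = 0, end = 10, n_intervals = 1,
               n_contigs = length(samples), n_samples = length(samples),
               contig_ids = "x", samples = paste(samples, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(retain_regions(mk_region(c("a", "b")))), 0)
  expect_equal(nrow(retain_regions(mk_region(c("a", "b", "c")))), 1)
  set.seed(13)
  iv <- random_intervals(300, max_pos = 2000,
                         samples = sprintf("s%d", 1:8))
  m <- merge_regions(iv)
  kept <- retain_regions(m, min_samples = 3)
  oracle <- m[vapply(strsplit(m$samples, ";"), length, integer(1)) >= 3, ]
  expect_equal(kept$start, oracle$start)
})

test_that("specificity classification follows the majority/recurrence rules", {
  mk_region <- function(contigs) {
    samples <- unique(sub("\\|.*", "", contigs))
    data.frame(chrom = "chr1", start = 0, end = 10,
               n_intervals = length(contigs), n_contigs = length(contigs),
               n_samples = length(samples),
               contig_ids = paste(contigs, collapse = ";"),
               samples = paste(samples, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  labels <- c(h1 = "heat", h2 = "heat", h3 = "heat", c1 = "control",
              c2 = "control")
  # 3 heat vs 1 control -> 0.75, SPECIFIC
  r <- specificity(mk_region(c("h1|a", "h2|b", "h3|c", "c1|d")), labels,
                   axis = "stress")
  expect_equal(r$specificity, 0.75)
  expect_equal(r$klass, "SPECIFIC")
  expect_equal(r$top_category, "heat")
  # 2 vs 2 -> 0.5, strict majority fails -> NONE (only 4 samples)
  r2 <- specificity(mk_region(c("h1|a", "h2|b", "c1|c", "c2|d")), labels,
                    axis = "stress")
  expect_equal(r2$specificity, 0.5)
  expect_equal(r2$klass, "NONE")
  # 12 samples spread over 8 categories, max 3/12 -> RECURRENT
  many <- sprintf("s%02d|k", 1:12)
  lab12 <- setNames(c(rep("st1", 3), sprintf("st%d", 2:8),
                      c("st2", "st3")), sprintf("s%02d", 1:12))
  r3 <- specificity(mk_region(many), lab12, axis = "stress")
  expect_equal(r3$klass, "RECURRENT")
  expect_equal(r3$specificity, 3 / 12)
  # unlabeled sample -> error naming it
  expect_error(specificity(mk_region(c("zz|a")), labels, axis = "stress"),
               "zz")
})

test_that("region annotation concatenates overlaps and applies the 2 kb rule", {
  g <- small_genome()
  regions <- merge_regions(data.frame(
    chrom = "chr1",
    start = c(g$copies$start[1], 500),
    end = c(g$copies$start[1] + 2500, 2000),
    contig_id = c("c1", "c2"), sample_id = c("s1", "s2"),
    stringsAsFactors = FALSE))
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(g$copies$start[1] + 2001,
                             g$copies$start[1] + 2400))
  genes$Name <- "gene1"
  genes$type <- "gene"
  ann <- annotate_regions(regions, genes = genes, tes = g$copies,
                          genome = g, min_seq_len = 2000)
  te_region <- ann[ann$start == g$copies$start[1], ]
  expect_true(grepl(g$copies$family[1], te_region$annotations))
  expect_true(grepl("gene1", te_region$annotations))
  expect_false(te_region$below_length)
  small <- ann[ann$start == 500, ]
  expect_true(small$below_length)
  seqs <- attr(ann, "sequences")
  expect_equal(length(seqs), 1)
  expect_equal(nchar(seqs[[1]]), 2500)
  # random regions: overlap set equals a brute-force interval scan
  set.seed(17)
  iv <- random_intervals(60, max_pos = 5000, max_len = 200)
  rr <- merge_regions(iv)
  feats <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                      start = sample.int(5000, 30), stringsAsFactors = FALSE)
  feats$end <- feats$start + sample.int(300, 30)
  feats$family <- sprintf("feat%d", 1:30)
  ann2 <- annotate_regions(rr, tes = feats)
  for (i in seq_len(nrow(rr))) {
    hit <- feats$family[feats$chrom == rr$chrom[i] &
                          feats$start < rr$end[i] & feats$end > rr$start[i]]
    got <- strsplit(ann2$annotations[i], ";")[[1]]
    expect_setequal(got[nzchar(got)], hit)
  }
  # missing chromosome in the genome is an error
  expect_error(annotate_regions(rr, genome = c(other = "ACGT")), "missing")
})
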