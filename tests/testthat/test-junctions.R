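test_that("junction records fuse 3' LTR tail to 5' LTR head", {
  fams <- small_families()
  g <- small_genome()
  lib <- build_junction_library(g)
  expect_equal(nrow(lib), nrow(g$copies))
  expect_true(all(nchar(lib$seq) == 600))
  expect_true(all(lib$junction_pos == 300))
  # record = last 300 bp + first 300 bp of the oriented element
  for (i in seq_len(nrow(lib))) {
    elem <- element_seq(g, lib$copy_id[i])
    expect_identical(lib$seq[i],
                     paste0(substr(elem, nchar(elem) - 299, nchar(elem)),
                            substr(elem, 1, 300)))
  }
  # a TWO_LTR circle contains the junction record exactly once per wrap
  cid <- lib$copy_id[1]
  circ <- simulate_eccdna_pool(g, c(TWO_LTR = 1), copies = cid,
                               seed = 1)[[1]]
  doubled <- paste0(circ$seq, circ$seq)
  expect_equal(sum(gregexpr(lib$seq[1], doubled, fixed = TRUE)[[1]] > 0), 1)
})

test_that("short LTRs truncate the junction flanks (min rule)", {
  fams <- make_family_panel(1, ltr_len = 120, internal_len = 1000, seed = 2)
  g <- build_genome(fams, setNames(1L, names(fams)), 20000, seed = 2)
  lib <- build_junction_library(g, flank = 300)
  expect_equal(nchar(lib$seq), 240)
  expect_equal(lib$junction_pos, 120)
  expect_equal(lib$tail_len, 120)
  expect_equal(lib$head_len, 120)
})

test_that("junction library is invariant to element strand", {
  fams <- small_families()
  fam <- fams[[1]]
  tsd <- "ACGTA"
  flank_l <- mobiloscope:::random_dna(500)
  flank_r <- mobiloscope:::random_dna(500)
  mk_truth <- function(start, end, strand, L = 300) {
    if (strand == "+") { l5 <- c(start, start + L); l3 <- c(end - L, end) }
    else { l5 <- c(end - L, end); l3 <- c(start, start + L) }
    data.frame(copy_id = "cp", family = fam$name, chrom = "chr",
               start = start, end = end, strand = strand,
               ltr5_start = l5[1], ltr5_end = l5[2],
               ltr3_start = l3[1], ltr3_end = l3[2],
               stringsAsFactors = FALSE)
  }
  plus_chrom <- paste0(flank_l, tsd, fam$consensus, tsd, flank_r)
  minus_chrom <- paste0(flank_l, tsd, revcomp(fam$consensus), tsd, flank_r)
  s <- nchar(flank_l) + 5
  e <- s + nchar(fam$consensus)
  lib_p <- build_junction_library(c(chr = plus_chrom), mk_truth(s, e, "+"))
  lib_m <- build_junction_library(c(chr = minus_chrom), mk_truth(s, e, "-"))
  expect_identical(lib_p$seq, lib_m$seq)
  expect_identical(lib_p$junction_pos, lib_m$junction_pos)
})

test_that("copies without LTR annotations are skipped with a warning", {
  g <- small_genome()
  cp <- g$copies
  cp$ltr5_start[1] <- NA
  expect_warning(lib <- build_junction_library(g, copies = cp), "skipped")
  expect_equal(nrow(lib), nrow(cp) - 1)
})

test_that("the >=5 bp both-sides rule is enforced at the boundary", {
  lib <- data.frame(copy_id = "cp", family = "f", seq = strrep("A", 600),
                    junction_pos = 300L, tail_len = 300L, head_len = 300L,
                    stringsAsFactors = FALSE)
  class(lib) <- c("junction_library", "data.frame")
  kept <- junction_spanning_reads(aln_row("a", "cp", 295, 310), lib)
  expect_equal(nrow(kept), 1)
  dropped <- junction_spanning_reads(aln_row("b", "cp", 296, 310), lib)
  expect_equal(nrow(dropped), 0)
  dropped2 <- junction_spanning_reads(aln_row("c", "cp", 200, 304), lib)
  expect_equal(nrow(dropped2), 0)
  expect_error(junction_spanning_reads(aln_row("d", "other", 0, 100), lib),
               "unknown")
})

test_that("tiled reads across a junction record match brute-force counting", {
  fams <- small_families()
  g <- small_genome()
  lib <- build_junction_library(g)[1, ]
  class(lib) <- c("junction_library", "data.frame")
  starts <- 0:(600 - 100)
  reads <- setNames(substring(lib$seq, starts + 1, starts + 100),
                    sprintf("t%03d", starts))
  aln <- naive_align(reads, setNames(lib$seq, lib$copy_id),
                     all_hits = TRUE)
  kept <- junction_spanning_reads(aln, lib, min_overlap = 5)
  oracle <- sum(vapply(starts, function(s)
    (300 - s) >= 5 && (s + 100 - 300) >= 5, logical(1)))
  expect_equal(oracle, 91)
  expect_equal(nrow(kept), oracle)
})

test_that("junction coverage sums per-base depth of non-duplicate reads", {
  lib <- data.frame(copy_id = c("cp1", "cp2"), family = c("f", "f"),
                    seq = rep(strrep("A", 600), 2),
                    junction_pos = 300L, tail_len = 300L, head_len = 300L,
                    stringsAsFactors = FALSE)
  one <- aln_row("a", "cp1", 250, 350)
  expect_equal(junction_signal(one, lib)$raw, c(100, 0))
  # identical coordinates collapse under dedup
  two <- mark_duplicates(rbind(one, aln_row("b", "cp1", 250, 350)))
  expect_equal(junction_signal(two, lib)$raw, c(100, 0))
  expect_equal(junction_signal(two, lib, dedup = FALSE)$raw, c(200, 0))
  # random offsets: equals an independent per-base pileup
  set.seed(5)
  offs <- sample(205:295, 50, replace = TRUE)
  aln <- do.call(rbind, lapply(seq_along(offs), function(i)
    aln_row(sprintf("r%d", i), "cp1", offs[i], offs[i] + 100)))
  aln <- mark_duplicates(aln)
  raw <- junction_signal(aln, lib)$raw[1]
  keep <- !aln$is_duplicate
  pileup <- tabulate(unlist(mapply(function(s, e) seq(s + 1, e),
                                   aln$start[keep], aln$end[keep])), 600)
  expect_equal(raw, sum(pileup))
})

test_that("normalization scales by total coverage and is depth-invariant", {
  sig <- data.frame(copy_id = "cp", family = "f", raw = 600,
                    stringsAsFactors = FALSE)
  ns <- normalize_signal(sig, 6e6, sample_id = "s1")
  expect_equal(ns$normalized, 100)
  expect_equal(normalize_signal(data.frame(copy_id = "cp", family = "f",
                                           raw = 0), 6e6)$normalized, 0)
  expect_error(normalize_signal(sig, 0), "> 0")

  # doubling sequencing depth changes the normalized signal by < 5%
  fams <- small_families()
  g <- small_genome()
  cid <- g$copies$copy_id[g$copies$family == names(fams)[1]]
  pool <- simulate_eccdna_pool(g, c(TWO_LTR = 1), copies = cid, seed = 6)
  lib <- build_junction_library(g)
  s1 <- mobility_signal(rca_reads(pool, depth = 40, seed = 7), lib, g,
                        sample_id = "d40")
  s2 <- mobility_signal(rca_reads(pool, depth = 80, seed = 8), lib, g,
                        sample_id = "d80")
  f1 <- sum(s1$normalized); f2 <- sum(s2$normalized)
  expect_gt(f1, 0)
  expect_lt(abs(f2 / f1 - 1), 0.05)
})

test_that("family aggregation is exactly additive", {
  sig <- data.frame(sample_id = "s1", copy_id = c("c1", "c2", "c3"),
                    family = c("f1", "f1", "f2"), raw = c(200, 300, 100),
                    normalized = c(2, 3, 1), is_genomic_control = FALSE,
                    stringsAsFactors = FALSE)
  fam <- family_signal(sig)
  expect_equal(fam$normalized[fam$family == "f1"], 5)
  expect_equal(fam$normalized[fam$family == "f2"], 1)
  # simulator: family signal equals the sum of its per-copy signals
  fams <- small_families()
  g <- small_genome()
  cid <- g$copies$copy_id[g$copies$family == names(fams)[1]]
  pool <- simulate_eccdna_pool(g, c(TWO_LTR = 1), copies = cid, seed = 9)
  lib <- build_junction_library(g)
  per_copy <- mobility_signal(rca_reads(pool, depth = 30, seed = 10),
                              lib, g, sample_id = "s")
  fam2 <- family_signal(per_copy)
  agg <- tapply(per_copy$normalized, per_copy$family, sum)
  expect_equal(fam2$normalized, as.numeric(agg[fam2$family]))
})

test_that("genomic reads yield no junction signal on a clean genome", {
  g <- small_genome()
  lib <- build_junction_library(g)
  w <- wgs_reads(g, depth = 10, seed = 11)
  ctrl <- genomic_control(w, lib, g)
  expect_true(all(ctrl$is_genomic_control))
  expect_true(all(ctrl$raw == 0))
  # an engineered tandem pair creating a real genomic tail-to-head junction
  fams <- small_families()
  fam <- fams[[1]]
  tandem_chrom <- paste0(mobiloscope:::random_dna(2000),
                         fam$consensus, fam$consensus,
                         mobiloscope:::random_dna(2000))
  s <- 2000; e <- s + nchar(fam$consensus)
  truth <- data.frame(copy_id = "tandem1", family = fam$name,
                      chrom = "chrT", start = s, end = e, strand = "+",
                      ltr5_start = s, ltr5_end = s + 300,
                      ltr3_start = e - 300, ltr3_end = e,
                      stringsAsFactors = FALSE)
  gt <- structure(list(chromosomes = c(chrT = tandem_chrom),
                       copies = truth, tsd_len = 5),
                  class = "synthetic_genome")
  libt <- build_junction_library(gt)
  wt <- wgs_reads(gt, depth = 20, seed = 12)
  ctrl_t <- genomic_control(wt, libt, gt)
  expect_gt(ctrl_t$raw[1], 0)
  # empty WGS input: zero-signal control with a warning
  empty <- mobiloscope:::new_read_set(character(0), character(0), NULL)
  expect_warning(z <- genomic_control(empty, lib, g), "empty")
  expect_true(all(z$raw == 0))
})
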