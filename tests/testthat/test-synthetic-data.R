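test_that("family consensus has the LTR-internal-LTR structure", {
  fams <- make_family_panel(1, ltr_len = 10, internal_len = 5, seed = 1)
  cons <- fams[[1]]$consensus
  expect_equal(nchar(cons), 25)
  expect_identical(substr(cons, 1, 10), substr(cons, 16, 25))

  # every consensus starts and ends with its own LTR, families dissimilar
  fams5 <- make_family_panel(5, ltr_len = 300, internal_len = 1000, seed = 2)
  for (f in fams5) {
    expect_identical(substr(f$consensus, 1, 300), f$ltr_seq)
    expect_identical(substr(f$consensus, nchar(f$consensus) - 299,
                            nchar(f$consensus)), f$ltr_seq)
  }
  ltrs <- vapply(fams5, `[[`, character(1), "ltr_seq")
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(mobiloscope:::seq_identity(ltrs[i], ltrs[j]), 0.8)
})

test_that("family panel generation is deterministic and validates input", {
  f1 <- make_family_panel(3, 50, 100, seed = 7)
  f2 <- make_family_panel(3, 50, 100, seed = 7)
  expect_identical(family_consensus(f1), family_consensus(f2))
  tmp1 <- tempfile(fileext = ".fa"); tmp2 <- tempfile(fileext = ".fa")
  write_family_fasta(f1, tmp1); write_family_fasta(f2, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_error(make_family_panel(0, 50, 100, 1), "n_families")
  expect_error(make_family_panel(1, 5, 100, 1), "ltr_len")
})

test_that("genome construction plants exact copies with TSDs", {
  fams <- small_families()
  famA <- names(fams)[1]
  # zero copies of a family -> no trace of it
  g0 <- build_genome(fams, setNames(c(0L, 2L), names(fams)),
                     chrom_len = 50000, seed = 3)
  expect_false(any(g0$copies$family == famA))
  expect_false(grepl(fams[[famA]]$consensus, g0$chromosomes[[1]],
                     fixed = TRUE))

  # divergence 0: exhaustive substring scan finds exactly the planted count
  g8 <- build_genome(fams, setNames(c(8L, 0L), names(fams)),
                     chrom_len = 120000, seed = 4)
  chrom <- g8$chromosomes[[1]]
  cons <- fams[[famA]]$consensus
  n_fwd <- sum(gregexpr(cons, chrom, fixed = TRUE)[[1]] > 0)
  n_rev <- sum(gregexpr(revcomp(cons), chrom, fixed = TRUE)[[1]] > 0)
  expect_equal(n_fwd + n_rev, 8)
  expect_equal(nrow(g8$copies), 8)

  # TSD: tsd_len bases left of every element equal the bases to its right
  g <- small_genome()
  t <- g$tsd_len
  for (i in seq_len(nrow(g$copies))) {
    cp <- g$copies[i, ]
    ch <- g$chromosomes[[cp$chrom]]
    expect_identical(substr(ch, cp$start - t + 1, cp$start),
                     substr(ch, cp$end + 1, cp$end + t))
  }
  # truth copies match their family consensus at divergence 0
  for (i in seq_len(nrow(g$copies)))
    expect_identical(element_seq(g, g$copies$copy_id[i]),
                     fams[[g$copies$family[i]]]$consensus)
})

test_that("eccDNA circle classes have the required structure", {
  fams <- small_families()
  g <- small_genome()
  famA <- names(fams)[1]
  cid <- g$copies$copy_id[g$copies$family == famA][1]
  ltr <- fams[[famA]]$ltr_seq
  elen <- nchar(fams[[famA]]$consensus)

  two <- simulate_eccdna_pool(g, c(TWO_LTR = 1), copies = cid, seed = 5)[[1]]
  expect_equal(nchar(two$seq), elen)
  junction_600 <- paste0(substr(two$seq, elen - 299, elen),
                         substr(two$seq, 1, 300))
  doubled <- paste0(two$seq, two$seq)
  expect_equal(sum(gregexpr(junction_600, doubled, fixed = TRUE)[[1]] > 0), 1)

  one <- simulate_eccdna_pool(g, c(ONE_LTR = 1), copies = cid, seed = 5)[[1]]
  expect_equal(nchar(one$seq), elen - 300)
  # exactly one LTR per wrap of the circle (two in the doubled sequence)
  expect_equal(sum(gregexpr(ltr, one$seq, fixed = TRUE)[[1]] > 0), 1)
  expect_equal(sum(gregexpr(ltr, paste0(one$seq, one$seq),
                            fixed = TRUE)[[1]] > 0), 2)

  frags <- simulate_eccdna_pool(g, c(FRAGMENT = 3), copies = cid, seed = 5)
  for (fr in frags) {
    expect_lt(nchar(fr$seq), elen)
    expect_false(grepl(ltr, paste0(fr$seq, fr$seq), fixed = TRUE))
    # 1-LTR and fragment circles never contain the tail-to-head junction
    expect_false(grepl(junction_600, paste0(fr$seq, fr$seq), fixed = TRUE))
  }
  expect_false(grepl(junction_600, paste0(one$seq, one$seq), fixed = TRUE))
  expect_error(simulate_eccdna_pool(g, c(TWO_LTR = 1), copies = "nope"),
               "truth")
})

test_that("rolling-circle reads wrap the closure at the expected rate", {
  fams <- small_families()
  g <- small_genome()
  cid <- g$copies$copy_id[1]
  pool <- simulate_eccdna_pool(g, c(FRAGMENT = 1), copies = cid, seed = 6)
  pool[[1]]$seq <- substr(element_seq(g, cid), 401, 1400)  # fixed 1 kb circle
  reads <- rca_reads(pool, depth = 100, read_len = 100, seed = 7)
  tr <- attr(reads, "truth")
  n <- nrow(tr)
  expect_equal(n, 1000)
  p_expect <- 99 / 1000
  obs <- mean(tr$crosses_closure)
  expect_lt(abs(obs - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))

  # error-free reads are exact substrings of the doubled circle
  doubled <- strrep(pool[[1]]$seq, 3)
  hit <- vapply(reads$seq, function(s)
    grepl(s, doubled, fixed = TRUE) || grepl(revcomp(s), doubled,
                                             fixed = TRUE), logical(1))
  expect_true(all(hit))

  # degenerate input: empty pool -> empty read set, no error
  empty <- rca_reads(structure(list(), class = "eccdna_pool"), depth = 10)
  expect_equal(nrow(empty), 0)
  expect_error(rca_reads(pool, depth = 1, read_len = 400, frag_len = 300),
               "read_len")
})

test_that("WGS read simulation: counts, exactness, determinism", {
  fams <- small_families()
  g <- build_genome(fams, setNames(c(0L, 0L), names(fams)),
                    chrom_len = 100000, seed = 8)
  w <- wgs_reads(g, depth = 10, read_len = 100, seed = 9)
  expect_equal(nrow(w), 10000)
  chrom <- g$chromosomes[[1]]
  idx <- sample.int(nrow(w), 50)
  for (i in idx) {
    s <- w$seq[i]
    expect_true(grepl(s, chrom, fixed = TRUE) ||
                  grepl(revcomp(s), chrom, fixed = TRUE))
  }
  # truth record reproduces each read when error_rate = 0
  tr <- attr(w, "truth")
  for (i in idx) {
    ref <- substr(chrom, tr$start[i] + 1, tr$start[i] + 100)
    expect_identical(w$seq[i],
                     if (tr$strand[i] == "-") revcomp(ref) else ref)
  }
  w2 <- wgs_reads(g, depth = 10, read_len = 100, seed = 9)
  expect_identical(w$seq, w2$seq)
})

test_that("accession panel generator matches its stated model", {
  p0 <- simulate_accession_panel(50, 5, effect_sizes = 0, seed = 1)
  expect_equal(p0$truth$r2m_generating, 0)
  p5 <- simulate_accession_panel(50, 5, effect_sizes = 1, clade_var = 0,
                                 resid_var = 1, seed = 1)
  expect_equal(p5$truth$r2m_generating, 0.5)
  expect_error(simulate_accession_panel(50, 5, clade_var = -1), "variance")
  # empirical variance decomposition converges to the spec components
  vf <- vc <- vr <- numeric(60)
  for (s in 1:60) {
    p <- simulate_accession_panel(300, 5, effect_sizes = 0.7,
                                  clade_var = 0.5, resid_var = 1, seed = s)
    fit <- fit_random_intercept_lmm(p$pcn[, 1], p$bioclim[[1]], p$clades)
    vf[s] <- var(fit$fitted_fixed); vc[s] <- fit$sigma2_clade
    vr[s] <- fit$sigma2_resid
  }
  expect_lt(abs(mean(vf) - 0.49), 0.08)
  expect_lt(abs(mean(vr) - 1), 0.08)
  # clade variance is noisy with 5 clades; check location only
  expect_lt(abs(median(vc) - 0.5), 0.3)
})
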