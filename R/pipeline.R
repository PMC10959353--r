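#' Simulate a complete multi-sample mobilome experiment
#'
#' Builds the full study structure end to end: a family panel, a genome
#' carrying full-length copies of each family, a sample sheet of mobilome
#' samples split across two genotypes and two stress conditions, and a
#' per-sample eccDNA pool with rolling-circle amplified reads. One family
#' (`active_family`, by default the first) is transpositionally active in
#' the "mutant" genotype only and produces 2-LTR circles there; a second
#' family produces fragment circles in every sample (the ubiquitous
#' non-mobile eccDNA background), and the remaining families produce no
#' circles at all. Fragment lengths are at least 55% of the internal
#' region so every sample's fragments of a copy mutually overlap and merge
#' into a single circle-forming region.
#'
#' @param seed Master integer seed; every random stage derives from it.
#' @param n_families Number of families (default 4).
#' @param copies_per_family Full-length copies per family (default 5).
#' @param genome_len Background chromosome length (default 500 kb).
#' @param ltr_len LTR length (default 300 bp).
#' @param internal_len Internal region length (default 4400 bp).
#' @param n_samples Number of mobilome samples (default 12; half mutant,
#'   half wild type).
#' @param circle_depth Mean per-circle read depth (default 20).
#' @param read_len Read length (default 100 bp).
#' @param error_rate Per-base read error rate (default 0).
#' @return list: `families`, `genome`, `samples` (sample sheet with
#'   genotype and stress), `pools` (per-sample `eccdna_pool`), `reads`
#'   (per-sample `read_set`), `active_family`, `background_family`.
#' @export
simulate_mobilome_experiment <- function(seed = 1, n_families = 4,
                                         copies_per_family = 5,
                                         genome_len = 500000,
                                         ltr_len = 300, internal_len = 4400,
                                         n_samples = 12, circle_depth = 20,
                                         read_len = 100, error_rate = 0) {
  stopifnot(n_families >= 2, n_samples >= 2)
  families <- make_family_panel(n_families, ltr_len, internal_len, seed)
  fam_names <- names(families)
  genome <- build_genome(families,
                         setNames(rep(copies_per_family, n_families),
                                  fam_names),
                         chrom_len = genome_len, seed = seed)
  active <- fam_names[1]
  background <- fam_names[2]
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    genotype = rep(c("mutant", "wild_type"), each = ceiling(n_samples / 2),
                   length.out = n_samples),
    stress = rep(c("control", "heat"), length.out = n_samples),
    stringsAsFactors = FALSE)
  active_copies <- genome$copies$copy_id[genome$copies$family == active]
  bg_copies <- genome$copies$copy_id[genome$copies$family == background]
  pools <- list()
  reads <- list()
  for (i in seq_len(n_samples)) {
    s_seed <- derive_seed(seed, "misc") + i
    bg_pool <- simulate_eccdna_pool(genome, c(FRAGMENT = 1),
                                    copies = bg_copies,
                                    fragment_min_frac = 0.55,
                                    seed = s_seed)
    pool <- if (samples$genotype[i] == "mutant") {
      two_ltr <- simulate_eccdna_pool(genome, c(TWO_LTR = 1),
                                      copies = active_copies, seed = s_seed)
      structure(c(two_ltr, bg_pool), class = "eccdna_pool")
    } else bg_pool
    pools[[samples$sample_id[i]]] <- pool
    reads[[samples$sample_id[i]]] <-
      rca_reads(pool, depth = circle_depth, read_len = read_len,
                error_rate = error_rate, seed = s_seed)
  }
  list(families = families, genome = genome, samples = samples,
       pools = pools, reads = reads, active_family = active,
       background_family = background, seed = seed)
}

#' Per-sample and per-family junction signals of an experiment
#'
#' Builds the tail-to-head junction library from the genome's truth
#' copies, computes each sample's normalized per-copy mobility signal, and
#' aggregates to families.
#'
#' @param exp Output of [simulate_mobilome_experiment()].
#' @param flank Junction flank (default 300 bp).
#' @param min_overlap Junction-spanning rule (default 5 bp).
#' @return list: `library`, `per_copy` (long data.frame over samples),
#'   `per_family` (from [family_signal()]).
#' @export
run_junction_pipeline <- function(exp, flank = 300, min_overlap = 5) {
  lib <- build_junction_library(exp$genome, flank = flank)
  per_copy <- do.call(rbind, lapply(exp$samples$sample_id, function(s) {
    mobility_signal(exp$reads[[s]], lib, exp$genome, sample_id = s,
                    min_overlap = min_overlap)
  }))
  list(library = lib, per_copy = per_copy,
       per_family = family_signal(per_copy))
}

#' Circle-forming regions of an experiment
#'
#' Generates assembled-contig proxies from each sample's circles, keeps
#' the top `n_top` per sample, maps them to the genome (split-aware),
#' merges overlapping intervals into circle-forming regions, retains
#' regions seen in at least `min_samples` samples, annotates them with
#' the truth TE copies, and classifies specificity on the stress and
#' genotype axes.
#'
#' @param exp Output of [simulate_mobilome_experiment()].
#' @param n_top Contigs kept per sample (default 10).
#' @param min_samples Region retention threshold (default 3).
#' @param contig_mm_per100 Mismatch budget for contig mapping (default 0;
#'   contigs from an error-free simulation match the reference exactly).
#' @return list: `regions` (retained, annotated), `specificity`
#'   (stress and genotype calls, rbind-ed), `intervals`.
#' @export
run_region_pipeline <- function(exp, n_top = 10, min_samples = 3,
                                contig_mm_per100 = 0) {
  all_intervals <- list()
  contig_samples <- character(0)
  for (s in exp$samples$sample_id) {
    contigs <- make_contigs(exp$pools[[s]], rotate = TRUE,
                            seed = exp$seed * 131L +
                              match(s, exp$samples$sample_id))
    if (!nrow(contigs)) next
    contigs$contig_id <- paste(s, contigs$contig_id, sep = "|")
    sel <- top_contigs(contigs, n = n_top)
    aln <- naive_align(setNames(sel$seq, sel$contig_id), exp$genome,
                       max_mm_per100 = contig_mm_per100, all_hits = TRUE)
    cs <- setNames(rep(s, nrow(sel)), sel$contig_id)
    contig_samples <- c(contig_samples, cs)
    all_intervals[[s]] <- contig_regions(aln, cs)
  }
  intervals <- do.call(rbind, all_intervals)
  regions <- retain_regions(merge_regions(intervals),
                            min_samples = min_samples)
  regions <- annotate_regions(regions, tes = exp$genome$copies,
                              genome = exp$genome)
  geno <- setNames(exp$samples$genotype, exp$samples$sample_id)
  stress <- setNames(exp$samples$stress, exp$samples$sample_id)
  spec <- rbind(specificity(regions, geno, axis = "genotype"),
                specificity(regions, stress, axis = "stress"))
  list(regions = regions, specificity = spec, intervals = intervals)
}
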