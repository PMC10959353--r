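#' Build a synthetic genome carrying full-length LTR-RT copies
#'
#' Inserts full-length copies of each family into a random background
#' chromosome. Each insertion is flanked by an exact target-site duplication
#' (TSD) of `tsd_len` bp, as created by integrase during transposition, and
#' may be placed on either strand. Per-copy divergence from the consensus is
#' modelled as uniform substitutions (no indels), mimicking post-insertion
#' mutation accumulation; the two LTRs of a diverged copy therefore drift
#' apart independently, as they do in real elements.
#'
#' @param families A `family_panel`.
#' @param copy_spec Named integer vector, family name -> number of
#'   full-length copies to insert.
#' @param chrom_len Background chromosome length in bp.
#' @param tsd_len TSD length in bp (default 5, typical of Copia-like
#'   integrases).
#' @param divergence Per-base substitution rate applied to each copy,
#'   in \[0, 0.1\].
#' @param seed Integer seed.
#' @param chrom_name Chromosome name.
#' @param min_gap Minimum distance between insertion points on the
#'   background, in bp.
#' @return An object of class `synthetic_genome`: list with `chromosomes`
#'   (named character vector), `copies` (truth data.frame with 0-based
#'   half-open element and per-copy LTR coordinates plus metadata), and
#'   `tsd_len`.
#' @export
build_genome <- function(families, copy_spec, chrom_len, tsd_len = 5,
                         divergence = 0, seed = 1, chrom_name = "chr1",
                         min_gap = 200) {
  stopifnot(inherits(families, "family_panel"))
  if (divergence < 0 || divergence > 0.1)
    stop("divergence must be in [0, 0.1]")
  copy_spec <- copy_spec[copy_spec > 0]
  fam_len <- vapply(names(copy_spec),
                    function(f) nchar(families[[f]]$consensus), numeric(1))
  total_insert <- sum((fam_len + tsd_len) * copy_spec)
  if (length(copy_spec) && total_insert >= chrom_len)
    stop("total inserted length exceeds chrom_len")

  with_seed(derive_seed(seed, "genome"), {
    background <- random_dna(chrom_len)
    n_copies <- sum(copy_spec)
    if (n_copies == 0) {
      return(structure(list(
        chromosomes = setNames(background, chrom_name),
        copies = empty_truth(), tsd_len = tsd_len),
        class = "synthetic_genome"))
    }
    # insertion points on the background, mutually distant, away from ends
    margin <- min_gap + tsd_len
    ok <- FALSE
    for (try in 1:50) {
      pts <- sort(sample.int(chrom_len - 2 * margin, n_copies) + margin)
      if (n_copies == 1 || min(diff(pts)) >= min_gap) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place copies without overlap; ",
                  "reduce copy counts or enlarge chrom_len")

    fam_of_copy <- rep(names(copy_spec), times = copy_spec)
    fam_of_copy <- sample(fam_of_copy)   # interleave families along the chromosome
    strands <- sample(c("+", "-"), n_copies, replace = TRUE)

    pieces <- character(0)
    rows <- vector("list", n_copies)
    prev <- 0L          # background consumed so far (0-based)
    out_len <- 0L       # length of output assembled so far
    for (i in seq_len(n_copies)) {
      fam <- families[[fam_of_copy[i]]]
      p <- pts[i]
      elem <- mutate_seq(fam$consensus, divergence)
      oriented <- if (strands[i] == "-") revcomp(elem) else elem
      tsd <- substr0(background, p, p + tsd_len)
      pieces <- c(pieces, substr0(background, prev, p), tsd, oriented)
      out_len <- out_len + (p - prev) + tsd_len
      start <- out_len                      # element start (0-based)
      end <- start + nchar(oriented)
      L <- nchar(fam$ltr_seq)
      if (strands[i] == "+") {
        ltr5 <- c(start, start + L); ltr3 <- c(end - L, end)
      } else {
        ltr5 <- c(end - L, end); ltr3 <- c(start, start + L)
      }
      rows[[i]] <- data.frame(
        copy_id = sprintf("%s_%s_%d", fam$name, chrom_name, start),
        family = fam$name, chrom = chrom_name,
        start = start, end = end, strand = strands[i],
        ltr5_start = ltr5[1], ltr5_end = ltr5[2],
        ltr3_start = ltr3[1], ltr3_end = ltr3[2],
        age = divergence * 100, gc = gc_content(oriented),
        dist_to_gene = NA_real_, meth_cg = NA_real_, meth_chg = NA_real_,
        meth_chh = NA_real_, stringsAsFactors = FALSE)
      out_len <- out_len + nchar(oriented)
      prev <- p           # TSD source bases are re-used as right flank
    }
    pieces <- c(pieces, substr0(background, prev, chrom_len))
    chrom <- paste(pieces, collapse = "")
    structure(list(chromosomes = setNames(chrom, chrom_name),
                   copies = do.call(rbind, rows), tsd_len = tsd_len),
              class = "synthetic_genome")
  })
}

empty_truth <- function() {
  data.frame(copy_id = character(0), family = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), ltr5_start = integer(0),
             ltr5_end = integer(0), ltr3_start = integer(0),
             ltr3_end = integer(0), age = numeric(0), gc = numeric(0),
             dist_to_gene = numeric(0), meth_cg = numeric(0),
             meth_chg = numeric(0), meth_chh = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosome(s), %d bp total, %d truth copies\n",
              length(x$chromosomes), sum(nchar(x$chromosomes)),
              nrow(x$copies)))
  invisible(x)
}

#' Total genome length of a synthetic genome
#' @param genome A `synthetic_genome`.
#' @return Total length in bp.
#' @export
genome_length <- function(genome) sum(nchar(genome$chromosomes))

#' Extract the oriented sequence of a truth copy
#'
#' Returns the element sequence in element orientation (5' LTR first);
#' minus-strand copies are reverse-complemented.
#'
#' @param genome A `synthetic_genome`.
#' @param copy_id A truth copy id.
#' @return DNA string of the full-length element.
#' @export
element_seq <- function(genome, copy_id) {
  row <- genome$copies[genome$copies$copy_id == copy_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown copy_id: ", copy_id)
  s <- substr0(genome$chromosomes[[row$chrom]], row$start, row$end)
  if (row$strand == "-") revcomp(s) else s
}

#' Write truth copies as BED6
#'
#' 0-based half-open, name = copy_id, score = 0.
#' @param genome A `synthetic_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(genome, path) {
  cp <- genome$copies
  bed <- data.frame(cp$chrom, cp$start, cp$end, cp$copy_id, 0L, cp$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write truth copies (with LTR child features) as GFF3
#'
#' Emits one `LTR_retrotransposon` feature per copy and two
#' `long_terminal_repeat` children; coordinates are converted to the 1-based
#' inclusive GFF3 convention.
#'
#' @param genome A `synthetic_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(genome, path) {
  cp <- genome$copies
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(cp))) {
    r <- cp[i, ]
    lines <- c(lines,
      sprintf("%s\tmobiloscope\tLTR_retrotransposon\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
              r$chrom, r$start + 1, r$end, r$strand, r$copy_id, r$family),
      sprintf("%s\tmobiloscope\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s;ltr=five_prime",
              r$chrom, r$ltr5_start + 1, r$ltr5_end, r$strand, r$copy_id),
      sprintf("%s\tmobiloscope\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s;ltr=three_prime",
              r$chrom, r$ltr3_start + 1, r$ltr3_end, r$strand, r$copy_id))
  }
  writeLines(lines, path)
  invisible(path)
}
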