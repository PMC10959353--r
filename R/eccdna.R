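#' Simulate an eccDNA pool from genomic LTR-RT copies
#'
#' Produces the three circle classes observed in mobilome data:
#' * `TWO_LTR` — the full-length linear element circularized so that the 3'
#'   LTR end abuts the 5' LTR start (the product of complete reverse
#'   transcription followed by end joining; diagnostic of mobility),
#' * `ONE_LTR` — a circle carrying a single LTR (LTR-LTR recombination or
#'   incomplete reverse transcription; not evidence of mobility),
#' * `FRAGMENT` — a proper substring of the internal region, circularized.
#'
#' Circles are stored as a linear sequence plus an implicit circular
#' topology; samplers use the doubled sequence for wrap-around.
#'
#' @param genome A `synthetic_genome`.
#' @param mix Named integer vector, circle kind -> count per source copy.
#'   Kinds: "TWO_LTR", "ONE_LTR", "FRAGMENT".
#' @param copies Character vector of source copy ids (default: all truth
#'   copies).
#' @param fragment_min_frac Minimum FRAGMENT length as a fraction of the
#'   internal region (default 0.25).
#' @param seed Integer seed.
#' @return An object of class `eccdna_pool`: list of circles, each with
#'   `circle_id`, `kind`, `seq`, `source_copy`, `family`.
#' @export
simulate_eccdna_pool <- function(genome, mix, copies = genome$copies$copy_id,
                                 fragment_min_frac = 0.25, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  kinds <- names(mix)
  if (!all(kinds %in% c("TWO_LTR", "ONE_LTR", "FRAGMENT")))
    stop("unknown circle kind in mix")
  missing <- setdiff(copies, genome$copies$copy_id)
  if (length(missing)) stop("copies not in genome truth: ",
                            paste(missing, collapse = ", "))
  with_seed(derive_seed(seed, "eccdna"), {
    out <- list()
    for (cid in copies) {
      row <- genome$copies[genome$copies$copy_id == cid, ]
      elem <- element_seq(genome, cid)
      ltr_len <- row$ltr5_end - row$ltr5_start
      for (kind in kinds) {
        n <- mix[[kind]]
        if (n <= 0) next
        if (kind != "FRAGMENT" &&
            (is.na(row$ltr5_start) || is.na(row$ltr3_start)))
          stop("copy ", cid, " lacks LTR annotations")
        for (j in seq_len(n)) {
          seq <- switch(kind,
            TWO_LTR = elem,
            # drop the 5' LTR: one LTR remains, junction string absent
            ONE_LTR = substr0(elem, ltr_len, nchar(elem)),
            FRAGMENT = {
              int_start <- ltr_len
              int_end <- nchar(elem) - ltr_len
              int_len <- int_end - int_start
              if (int_len < 50) stop("internal region too short for FRAGMENT")
              fmin <- max(50, floor(int_len * fragment_min_frac))
              flen <- sample(seq(fmin, int_len - 1), 1)
              fstart <- int_start + sample.int(int_len - flen + 1, 1) - 1
              substr0(elem, fstart, fstart + flen)
            })
          out[[length(out) + 1L]] <- list(
            circle_id = sprintf("%s_%s_%d", cid, kind, j),
            kind = kind, seq = seq, source_copy = cid, family = row$family)
        }
      }
    }
    structure(out, class = "eccdna_pool")
  })
}

#' @export
print.eccdna_pool <- function(x, ...) {
  kinds <- table(vapply(x, `[[`, character(1), "kind"))
  cat(sprintf("eccdna_pool: %d circles (%s)\n", length(x),
              paste(names(kinds), kinds, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Truth table of an eccDNA pool
#' @param pool An `eccdna_pool`.
#' @return data.frame with circle_id, kind, source_copy, family, length.
#' @export
eccdna_truth <- function(pool) {
  data.frame(circle_id = vapply(pool, `[[`, character(1), "circle_id"),
             kind = vapply(pool, `[[`, character(1), "kind"),
             source_copy = vapply(pool, `[[`, character(1), "source_copy"),
             family = vapply(pool, `[[`, character(1), "family"),
             length = vapply(pool, function(c) nchar(c$seq), numeric(1)),
             stringsAsFactors = FALSE)
}

new_read_set <- function(ids, seqs, truth, paired = FALSE) {
  rs <- data.frame(read_id = ids, seq = seqs, stringsAsFactors = FALSE)
  attr(rs, "truth") <- truth
  attr(rs, "paired") <- paired
  class(rs) <- c("read_set", "data.frame")
  rs
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, mutate_seq, character(1), rate = error_rate,
         USE.NAMES = FALSE)
}

#' Simulate rolling-circle-amplified reads from an eccDNA pool
#'
#' Models the read structure produced by rolling-circle amplification of
#' circular templates: fragments are sampled uniformly on the circle with
#' wrap-around (concatemeric), so a read crosses the circle closure point
#' with expected frequency `read_len / circle_len`. Errors are uniform
#' substitutions.
#'
#' @param pool An `eccdna_pool`.
#' @param depth Mean per-circle fold coverage.
#' @param read_len Read length in bp.
#' @param frag_len Mean fragment length in bp (>= read_len); only the first
#'   `read_len` bases of a fragment are sequenced (single-end model).
#' @param error_rate Per-base substitution rate.
#' @param seed Integer seed.
#' @return A `read_set` (data.frame of read_id, seq) whose `"truth"`
#'   attribute records each read's source circle, 0-based circular offset
#'   and strand.
#' @export
rca_reads <- function(pool, depth, read_len = 100, frag_len = 300,
                      error_rate = 0, seed = 1) {
  if (read_len > frag_len) stop("read_len must be <= frag_len")
  with_seed(derive_seed(seed, "rca"), {
    ids <- seqs <- character(0)
    tr <- list()
    for (circ in pool) {
      clen <- nchar(circ$seq)
      n <- round(depth * clen / read_len)
      if (n <= 0) next
      reps <- max(2L, ceiling((frag_len * 2 + read_len) / clen) + 1L)
      tiled <- strrep(circ$seq, reps)
      starts <- sample.int(clen, n, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      frags <- pmin(pmax(round(rnorm(n, frag_len, 0.1 * frag_len)),
                         read_len), nchar(tiled) - starts)
      raw <- substring(tiled, starts + 1, starts + frags)
      # sequencing starts from a random fragment end
      rc <- strands == "-"
      raw[rc] <- revcomp(raw[rc])
      reads <- substr(raw, 1, read_len)
      rid <- sprintf("%s_r%d", circ$circle_id, seq_len(n))
      ids <- c(ids, rid)
      seqs <- c(seqs, reads)
      tr[[length(tr) + 1L]] <- data.frame(
        read_id = rid, circle_id = circ$circle_id, offset = starts,
        frag_len = frags, strand = strands,
        crosses_closure = (starts + read_len > clen & strands == "+") |
          (starts + frags > clen &
             starts + frags - read_len < clen & strands == "-"),
        stringsAsFactors = FALSE)
    }
    truth <- if (length(tr)) do.call(rbind, tr) else
      data.frame(read_id = character(0), circle_id = character(0),
                 offset = integer(0), frag_len = integer(0),
                 strand = character(0), crosses_closure = logical(0),
                 stringsAsFactors = FALSE)
    reads <- new_read_set(ids, apply_errors(seqs, error_rate), truth)
    reads
  })
}

#' Simulate whole-genome shotgun reads
#'
#' Uniform linear sampling from the genome; single-end, substitution errors
#' only.
#'
#' @param genome A `synthetic_genome`.
#' @param depth Mean fold coverage.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution rate.
#' @param seed Integer seed.
#' @return A `read_set`; its `"truth"` attribute records chromosome,
#'   0-based start and strand per read.
#' @export
wgs_reads <- function(genome, depth, read_len = 100, error_rate = 0,
                      seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  with_seed(derive_seed(seed, "wgs"), {
    lens <- nchar(genome$chromosomes)
    total <- sum(lens)
    n <- round(depth * total / read_len)
    chrom_idx <- sample.int(length(lens), n, replace = TRUE,
                            prob = lens / total)
    starts <- floor(runif(n) * (lens[chrom_idx] - read_len)) # 0-based
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$chromosomes[chrom_idx], starts + 1,
                      starts + read_len)
    seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
    ids <- sprintf("wgs_r%d", seq_len(n))
    truth <- data.frame(read_id = ids,
                        chrom = names(genome$chromosomes)[chrom_idx],
                        start = starts, strand = strands,
                        stringsAsFactors = FALSE)
    new_read_set(ids, apply_errors(seqs, error_rate), truth)
  })
}

#' Generate assembled-contig proxies from an eccDNA pool
#'
#' Stands in for de novo assembly of rolling-circle amplified reads: each
#' selected circle yields one contig, optionally rotated to a random origin
#' (assemblies of circular templates start at an arbitrary point) and
#' trimmed at the ends.
#'
#' @param pool An `eccdna_pool`.
#' @param rotate Rotate each contig to a random circular origin.
#' @param trim Maximum bases trimmed from each contig end.
#' @param seed Integer seed.
#' @return data.frame with contig_id, circle_id, family, seq, length.
#' @export
make_contigs <- function(pool, rotate = TRUE, trim = 0, seed = 1) {
  with_seed(derive_seed(seed, "contigs"), {
    rows <- lapply(seq_along(pool), function(i) {
      circ <- pool[[i]]
      s <- circ$seq
      if (rotate) {
        r <- sample.int(nchar(s), 1) - 1L
        s <- paste0(substr0(s, r, nchar(s)), substr0(s, 0, r))
      }
      if (trim > 0) {
        t1 <- sample.int(trim + 1L, 1) - 1L
        t2 <- sample.int(trim + 1L, 1) - 1L
        if (nchar(s) > t1 + t2) s <- substr0(s, t1, nchar(s) - t2)
      }
      data.frame(contig_id = sprintf("contig_%s", circ$circle_id),
                 circle_id = circ$circle_id, family = circ$family,
                 seq = s, length = nchar(s), stringsAsFactors = FALSE)
    })
    if (!length(rows)) return(data.frame(
      contig_id = character(0), circle_id = character(0),
      family = character(0), seq = character(0), length = numeric(0),
      stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}
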