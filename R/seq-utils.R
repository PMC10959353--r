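DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' @param n Sequence length in bp.
#' @return A single character string over A/C/G/T.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Reverse complement(s) of `x`.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Uniform substitution mutations at the given per-base rate; no indels.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- rbinom(1, length(chars), rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Fraction of identical positions between two equal-length strings.
seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

gc_content <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * mean(chars %in% c("G", "C"))
}

# Substring with 0-based half-open coordinates (internal convention).
substr0 <- function(seq, start, end) {
  substr(seq, start + 1, end)
}

# Derive a stream-specific seed from a master seed so independent
# sub-simulations do not perturb each other.
derive_seed <- function(seed, stream) {
  offsets <- c(families = 11L, genome = 23L, eccdna = 37L, rca = 51L,
               wgs = 67L, panel = 83L, downsample = 97L, contigs = 113L,
               misc = 127L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 2654435 + as.numeric(off) * 40503) %%
               2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
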