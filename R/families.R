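#' Simulate a panel of LTR retrotransposon families
#'
#' Each family is modelled as a consensus sequence consisting of an internal
#' coding region flanked by two identical long terminal repeats (LTRs), the
#' structure produced by complete reverse transcription of an LTR-RT. Family
#' sequences are drawn independently at random, which keeps pairwise LTR
#' identity far below the 80% dissimilarity bound enforced here, so reads
#' cross-map between families only by chance.
#'
#' @param n_families Number of families (>= 1).
#' @param ltr_len LTR length in bp (>= 10).
#' @param internal_len Internal region length in bp (>= 0).
#' @param seed Integer seed; the same seed reproduces the same panel.
#' @param classification Optional character vector of family superfamilies
#'   ("RLC" = Copia-like, "RLG" = Gypsy-like); recycled. Defaults to
#'   alternating RLC/RLG.
#' @return An object of class `family_panel`: a list of families, each with
#'   `name`, `classification`, `ltr_seq`, `internal_seq` and `consensus`
#'   (`ltr_seq + internal_seq + ltr_seq`).
#' @examples
#' fams <- make_family_panel(2, ltr_len = 50, internal_len = 200, seed = 1)
#' nchar(fams[[1]]$consensus)  # 300
#' @export
make_family_panel <- function(n_families, ltr_len, internal_len, seed,
                              classification = NULL) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (ltr_len < 10) stop("ltr_len must be >= 10")
  if (internal_len < 0) stop("internal_len must be >= 0")
  if (is.null(classification))
    classification <- rep(c("RLC", "RLG"), length.out = n_families)
  classification <- rep(classification, length.out = n_families)
  stopifnot(all(classification %in% c("RLC", "RLG")))

  with_seed(derive_seed(seed, "families"), {
    fams <- vector("list", n_families)
    ltrs <- character(0)
    for (i in seq_len(n_families)) {
      repeat {
        ltr <- random_dna(ltr_len)
        if (all(vapply(ltrs, function(x) seq_identity(x, ltr) < 0.8,
                       logical(1)))) break
      }
      ltrs <- c(ltrs, ltr)
      internal <- random_dna(internal_len)
      name <- sprintf("%s_syn%03d", classification[i], i)
      fams[[i]] <- structure(
        list(name = name, classification = classification[i],
             ltr_seq = ltr, internal_seq = internal,
             consensus = paste0(ltr, internal, ltr)),
        class = "ltr_family")
    }
    names(fams) <- vapply(fams, `[[`, character(1), "name")
    structure(fams, class = "family_panel")
  })
}

#' @export
print.family_panel <- function(x, ...) {
  cat(sprintf("family_panel with %d families\n", length(x)))
  for (f in x)
    cat(sprintf("  %s (%s): LTR %d bp, internal %d bp, consensus %d bp\n",
                f$name, f$classification, nchar(f$ltr_seq),
                nchar(f$internal_seq), nchar(f$consensus)))
  invisible(x)
}

#' Consensus sequences of a family panel as a named character vector
#' @param families A `family_panel`.
#' @return Named character vector of consensus sequences.
#' @export
family_consensus <- function(families) {
  setNames(vapply(families, `[[`, character(1), "consensus"),
           vapply(families, `[[`, character(1), "name"))
}

#' Write family consensus sequences to FASTA
#' @param families A `family_panel`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(families, path) {
  write_fasta(family_consensus(families), path)
}
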