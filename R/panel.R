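#' Simulate a multi-accession pCN panel with clade structure
#'
#' Generates per-accession proxy copy numbers under the same random-intercept
#' model the association stage fits:
#' `pcn = baseline + sum_v beta[v] * bioclim[v] + u[clade] + e`,
#' with `u ~ N(0, clade_var)`, `e ~ N(0, resid_var)` and standard-normal
#' bioclimatic covariates, truncated at 0 (copy numbers are non-negative;
#' with the default baseline truncation is negligible). The generating
#' marginal R2 — fixed-effect variance over total — is recorded per family
#' in the `truth` element so recovery can be checked against it.
#'
#' @param n_accessions Number of accessions.
#' @param n_clades Number of clades (accessions assigned in balanced
#'   round-robin).
#' @param effect_sizes Numeric vector (one family) or matrix
#'   (variables x families) of fixed-effect coefficients per standardized
#'   bioclimatic variable.
#' @param clade_var Random-intercept (clade) variance, >= 0.
#' @param resid_var Residual variance, >= 0.
#' @param baseline Grand-mean pCN (keeps truncation at 0 inert).
#' @param seed Integer seed.
#' @return list with `pcn` (accessions x families matrix), `bioclim`
#'   (accessions x variables data.frame), `clades` (character vector),
#'   `truth` (per-family generating R2m and components).
#' @export
simulate_accession_panel <- function(n_accessions = 320, n_clades = 5,
                                     effect_sizes = 0.5, clade_var = 1,
                                     resid_var = 1, baseline = 10,
                                     seed = 1) {
  if (clade_var < 0 || resid_var < 0)
    stop("variance components must be >= 0")
  if (is.null(dim(effect_sizes)))
    effect_sizes <- matrix(effect_sizes, ncol = 1,
                           dimnames = list(NULL, "fam1"))
  n_var <- nrow(effect_sizes)
  n_fam <- ncol(effect_sizes)
  if (is.null(colnames(effect_sizes)))
    colnames(effect_sizes) <- sprintf("fam%d", seq_len(n_fam))
  with_seed(derive_seed(seed, "panel"), {
    clades <- sprintf("clade%d", rep(seq_len(n_clades),
                                     length.out = n_accessions))
    bioclim <- as.data.frame(matrix(rnorm(n_accessions * n_var),
                                    ncol = n_var))
    names(bioclim) <- sprintf("bio%d", seq_len(n_var))
    u <- rnorm(n_clades, 0, sqrt(clade_var))
    pcn <- matrix(0, n_accessions, n_fam,
                  dimnames = list(sprintf("acc%03d", seq_len(n_accessions)),
                                  colnames(effect_sizes)))
    for (f in seq_len(n_fam)) {
      fixed <- as.matrix(bioclim) %*% effect_sizes[, f]
      y <- baseline + fixed + u[as.integer(factor(clades))] +
        rnorm(n_accessions, 0, sqrt(resid_var))
      pcn[, f] <- pmax(y, 0)
    }
    var_fixed <- colSums(effect_sizes^2)   # covariates are iid N(0,1)
    truth <- data.frame(
      family = colnames(effect_sizes),
      var_fixed = var_fixed, clade_var = clade_var, resid_var = resid_var,
      r2m_generating = var_fixed / (var_fixed + clade_var + resid_var),
      stringsAsFactors = FALSE)
    list(pcn = pcn, bioclim = bioclim, clades = clades, truth = truth)
  })
}

#' Fixed-effect size achieving a target generating marginal R2
#'
#' For a single standardized covariate,
#' `beta = sqrt(r2m (clade_var + resid_var) / (1 - r2m))`.
#'
#' @param r2m Target marginal R2 in \[0, 1).
#' @param clade_var,resid_var Variance components of the panel.
#' @return The coefficient beta.
#' @export
effect_for_r2m <- function(r2m, clade_var = 1, resid_var = 1) {
  stopifnot(r2m >= 0, r2m < 1)
  sqrt(r2m * (clade_var + resid_var) / (1 - r2m))
}

#' Write panel tables to TSV
#' @param panel Output of [simulate_accession_panel()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_panel_tsv <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pcn <- data.frame(accession = rownames(panel$pcn), clade = panel$clades,
                    panel$pcn, check.names = FALSE)
  write.table(pcn, file.path(dir, "pcn.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bio <- data.frame(accession = rownames(panel$pcn), panel$bioclim)
  write.table(bio, file.path(dir, "bioclim.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
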