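#' Fit a random-intercept linear mixed model by REML
#'
#' Model: `y = b0 + b1 * x + u[group] + e`, with `u ~ N(0, sigma2_clade)`
#' and `e ~ N(0, sigma2_resid)`. The REML criterion is profiled down to a
#' one-dimensional optimization over the variance ratio
#' `lambda = sigma2_clade / sigma2_resid`; for a single grouping factor the
#' marginal covariance inverse has the closed form
#' `(I + lambda J)^-1 = I - lambda/(1 + lambda n_j) J` per group, so each
#' evaluation is O(n). Fixed-effect p-values are Wald (normal reference),
#' matching the default summaries of common mixed-model software.
#'
#' @param y Numeric response.
#' @param x Numeric covariate (single fixed effect besides the intercept).
#' @param group Clade labels (factor or character), >= 2 levels.
#' @return An `lmm_fit` list: `beta` (intercept, slope), `se`, `p_wald`,
#'   `sigma2_clade`, `sigma2_resid`, `loglik_reml`, `n`, `n_groups`,
#'   `fitted_fixed`.
#' @export
fit_random_intercept_lmm <- function(y, x, group) {
  ok <- is.finite(y) & is.finite(x) & !is.na(group)
  y <- y[ok]; x <- x[ok]; group <- factor(group[ok])
  n <- length(y); g <- nlevels(group)
  if (g < 2) stop("need >= 2 groups; use a plain linear model otherwise")
  if (n <= g + 2) stop("too few observations")
  if (sd(x) == 0) stop("covariate is constant")
  X <- cbind(`(Intercept)` = 1, x = x)
  p <- ncol(X)
  gi <- as.integer(group)
  ng <- tabulate(gi, nbins = g)

  # X' V0^-1 X, X' V0^-1 y, y' V0^-1 y for V0 = I + lambda Z Z'
  gls_parts <- function(lambda) {
    w <- lambda / (1 + lambda * ng)          # per-group shrinkage
    sx <- rowsum(X, gi); sy <- rowsum(y, gi) # group sums
    XtX <- crossprod(X) - crossprod(sx * sqrt(w))
    Xty <- crossprod(X, y) - crossprod(sx, sy * w)
    yty <- sum(y * y) - sum(w * sy^2)
    list(XtX = XtX, Xty = Xty, yty = yty,
         logdetV = sum(log1p(lambda * ng)))
  }
  reml_crit <- function(lambda) {
    pr <- gls_parts(lambda)
    beta <- solve(pr$XtX, pr$Xty)
    q <- max(pr$yty - 2 * sum(beta * pr$Xty) + drop(crossprod(beta, pr$XtX %*% beta)),
             .Machine$double.eps)
    (n - p) * log(q) + pr$logdetV + determinant(pr$XtX)$modulus[1]
  }
  opt <- optimize(function(t) reml_crit(exp(t)), interval = c(-12, 12))
  lambda <- exp(opt$minimum)
  if (reml_crit(0) <= opt$objective) lambda <- 0  # boundary: no clade variance

  pr <- gls_parts(lambda)
  beta <- drop(solve(pr$XtX, pr$Xty))
  q <- max(pr$yty - 2 * sum(beta * pr$Xty) +
             drop(crossprod(beta, pr$XtX %*% beta)), 0)
  sigma2_resid <- q / (n - p)
  sigma2_clade <- lambda * sigma2_resid
  covb <- solve(pr$XtX) * sigma2_resid
  se <- sqrt(diag(covb))
  z <- beta / se
  loglik <- -0.5 * ((n - p) * log(2 * pi * sigma2_resid) + pr$logdetV +
                      determinant(pr$XtX)$modulus[1] + (n - p))
  structure(list(beta = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 p_wald = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 sigma2_clade = sigma2_clade, sigma2_resid = sigma2_resid,
                 loglik_reml = as.numeric(loglik), n = n, n_groups = g,
                 lambda = lambda,
                 fitted_fixed = drop(X %*% beta)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("random-intercept LMM (REML): n=%d, groups=%d\n", x$n,
              x$n_groups))
  cat(sprintf("  beta: %s\n",
              paste(sprintf("%s=%.4g (p=%.3g)", names(x$beta), x$beta,
                            x$p_wald), collapse = ", ")))
  cat(sprintf("  sigma2_clade=%.4g sigma2_resid=%.4g logLik(REML)=%.4g\n",
              x$sigma2_clade, x$sigma2_resid, x$loglik_reml))
  invisible(x)
}

#' Marginal R2 of a mixed-model fit
#'
#' Variance explained by the fixed effects alone:
#' `R2m = Var(X beta) / (Var(X beta) + sigma2_clade + sigma2_resid)`
#' (the Nakagawa–Schielzeth decomposition for Gaussian models).
#'
#' @param fit An `lmm_fit`.
#' @return Marginal R2 in \[0, 1).
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  var_f <- var(fit$fitted_fixed)
  total <- var_f + fit$sigma2_clade + fit$sigma2_resid
  if (total <= 0) stop("all variance components are zero; R2m undefined")
  var_f / total
}

#' Associate pCNs with bioclimatic variables
#'
#' One model per (family, variable): the family's pCN as response, the
#' variable as a single fixed effect, and the accession clade as a random
#' intercept to absorb population structure. Significance is the per-test
#' Wald p < `alpha` (no multiple-testing correction by default; set
#' `adjust = "BH"` for Benjamini-Hochberg). With `random_effect = FALSE`
#' (or when only one clade is present, with a warning) an ordinary linear
#' model is fitted instead and R2m is the classical R2.
#'
#' @param pcn Matrix or data.frame, accessions x families.
#' @param bioclim data.frame of covariates, rows matching `pcn` accessions.
#' @param clades Clade label per accession.
#' @param alpha Significance level (default 0.05).
#' @param random_effect Use the random-intercept model (default TRUE).
#' @param adjust "none" (default) or "BH".
#' @return data.frame: family, variable, marginal_r2, p_value, significant,
#'   n_used, method.
#' @export
associate_bioclim <- function(pcn, bioclim, clades, alpha = 0.05,
                              random_effect = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pcn <- as.matrix(pcn)
  if (nrow(pcn) != nrow(bioclim) || nrow(pcn) != length(clades))
    stop("accessions must align across pcn, bioclim and clades")
  single_clade <- length(unique(clades[!is.na(clades)])) < 2
  if (single_clade && random_effect) {
    warning("single clade: falling back to ordinary linear models")
    random_effect <- FALSE
  }
  res <- list()
  for (fam in colnames(pcn)) {
    for (v in colnames(bioclim)) {
      y <- pcn[, fam]; x <- bioclim[[v]]
      ok <- is.finite(y) & is.finite(x) & !is.na(clades)
      n_drop <- sum(!ok)
      if (n_drop > 0)
        message(sprintf("%s ~ %s: dropped %d accession(s) with missing values",
                        fam, v, n_drop))
      if (random_effect) {
        fit <- fit_random_intercept_lmm(y[ok], x[ok], clades[ok])
        r2 <- marginal_r2(fit)
        pv <- fit$p_wald[["x"]]
        method <- "lmm"
      } else {
        m <- lm(y[ok] ~ x[ok])
        r2 <- summary(m)$r.squared
        pv <- summary(m)$coefficients[2, 4]
        method <- "lm"
      }
      res[[length(res) + 1L]] <- data.frame(
        family = fam, variable = v, marginal_r2 = r2, p_value = pv,
        n_used = sum(ok), method = method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  p_use <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_use < alpha
  out
}
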