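#' Marginal association scan with optional structure covariates
#'
#' For each site, ordinary least squares of the phenotype on (intercept,
#' dosage, covariates), computed for all sites at once by residualizing the
#' phenotype and every dosage column on the covariate block
#' (Frisch-Waugh-Lovell), which reproduces the per-site joint fit exactly.
#' Dosages are not variance-standardized, so effects are on the allele-count
#' scale. Standard errors come from the per-site residual variance with
#' `M - 2 - #covariates` degrees of freedom and two-sided t-test p-values.
#'
#' Sites whose dosage is collinear with the covariate block (zero residual
#' variance in the dosage) are flagged with `NA` estimates and excluded from
#' downstream ascertainment.
#'
#' @param gwas A `genotype_panel` (the GWAS panel).
#' @param pheno A phenotype object from [environmental_phenotype()] /
#'   [heritable_phenotype()], or a bare numeric vector of length M.
#' @param covariates List of `"structure_axis"` objects (standardized) to
#'   include as nuisance covariates; empty list for the uncorrected scan.
#' @param model_tag Label recording the correction used (stored with the
#'   estimates; defaults to `"none"` or `"custom"` depending on covariates).
#' @return An object of class `"effect_estimates"`: a data frame with columns
#'   `site_id`, `beta_hat`, `se`, `p`, plus attributes `model_tag`, `df` and
#'   `omega` (matrix of per-site nuisance coefficients, intercept first).
#' @examples
#' pair <- simulate_tree_panels(tree_demography(), n_per_pop = 50,
#'                              target_sites = 300, seed = 11)
#' ph <- environmental_phenotype(pair$gwas, "population_shift", delta = 0.1,
#'                               seed = 12)
#' eff <- marginal_gwas(pair$gwas, ph)
#' head(eff)
#' @export
marginal_gwas <- function(gwas, pheno, covariates = list(), model_tag = NULL) {
  stopifnot(inherits(gwas, "genotype_panel"))
  y <- if (is.numeric(pheno)) pheno else pheno$y
  M <- n_individuals(gwas)
  if (length(y) != M) stop("phenotype length does not match the GWAS panel")
  covmat <- if (length(covariates)) {
    do.call(cbind, lapply(covariates, function(cv) {
      if (inherits(cv, "structure_axis")) cv$values else as.numeric(cv)
    }))
  } else {
    NULL
  }
  design <- cbind(intercept = rep(1, M), covmat)
  qr_c <- qr(design)
  if (qr_c$rank < ncol(design)) {
    stop("covariate block is rank deficient (a covariate is collinear with the intercept or another covariate)")
  }
  yr <- qr.resid(qr_c, y)
  G <- gwas$dosages
  Gr <- qr.resid(qr_c, G)
  sgg <- colSums(Gr^2)
  df <- M - 2L - (ncol(design) - 1L)
  ok <- sgg > 1e-10
  beta <- se <- p <- rep(NA_real_, ncol(G))
  beta[ok] <- as.vector(crossprod(Gr[, ok, drop = FALSE], yr)) / sgg[ok]
  rss <- sum(yr^2) - beta[ok]^2 * sgg[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / df / sgg[ok])
  tt <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tt), df)

  # nuisance coefficients: full-model covariate slopes recovered from the
  # covariate-only fits, omega_l = coef(y ~ C) - coef(g_l ~ C) * beta_l
  cf_y <- qr.coef(qr_c, y)
  cf_g <- qr.coef(qr_c, G)
  omega <- matrix(NA_real_, nrow(cf_g), ncol(G),
                  dimnames = list(rownames(cf_g), gwas$site_ids))
  omega[, ok] <- cf_y - sweep(cf_g[, ok, drop = FALSE], 2L, beta[ok], "*")

  out <- data.frame(site_id = gwas$site_ids, beta_hat = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "model_tag") <- model_tag %||%
    (if (length(covariates)) "custom" else "none")
  attr(out, "df") <- df
  attr(out, "omega") <- omega
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Ascertain the top associated sites
#'
#' Returns the `S` site ids with the smallest p-values, ties broken by
#' ascending site index; sites flagged as invalid (rank-deficient) are
#' excluded. Deterministic.
#'
#' @param effects An `"effect_estimates"` object.
#' @param S Number of sites to ascertain.
#' @return Character vector of `S` site ids, ordered by significance.
#' @export
ascertain_top <- function(effects, S) {
  valid <- which(!is.na(effects$p))
  if (S > length(valid)) {
    stop(sprintf("requested S=%d sites but only %d valid sites are available",
                 S, length(valid)))
  }
  ord <- valid[order(effects$p[valid], valid)]
  effects$site_id[ord[seq_len(S)]]
}
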