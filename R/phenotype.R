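new_phenotype_set <- function(y, u, e, c, h2, delta, pattern,
                              causal_sites = NULL, true_betas = NULL,
                              theta = NA_real_, alpha = NA_real_,
                              sigma_i2 = NA_real_) {
  stopifnot(length(y) == length(u), length(y) == length(e),
            length(y) == length(c), isTRUE(all.equal(y, u + e)))
  structure(list(y = y, u = u, e = e, c = c, h2 = h2, delta = delta,
                 pattern = pattern, causal_sites = causal_sites,
                 true_betas = true_betas, theta = theta, alpha = alpha,
                 sigma_i2 = sigma_i2),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: M=%d, pattern=%s, delta=%g, h2=%g%s\n",
              length(x$y), x$pattern, x$delta, x$h2,
              if (is.null(x$causal_sites)) "" else
                sprintf(", %d causal sites (theta=%g, alpha=%g)",
                        length(x$causal_sites), x$theta, x$alpha)))
  invisible(x)
}

## expected environmental effect per individual under a confounding pattern
confounder_vector <- function(panel, pattern, delta,
                              diagonal_style = "gradient",
                              deme = c(1, 4)) {
  M <- n_individuals(panel)
  switch(pattern,
    none = rep(0, M),
    population_shift = {
      pops <- unique(panel$labels)
      if (length(pops) != 2) {
        stop("population_shift needs a panel with exactly two populations")
      }
      ifelse(panel$labels == pops[2], delta, 0)
    },
    latitude = {
      if (is.null(panel$coords)) stop("latitude pattern needs grid coordinates")
      (panel$coords[, "row"] - 1) * delta / 5
    },
    diagonal = {
      if (is.null(panel$coords)) stop("diagonal pattern needs grid coordinates")
      if (diagonal_style == "gradient") {
        (panel$coords[, "row"] + panel$coords[, "col"]) / 2 * delta / 5
      } else {
        ifelse(panel$coords[, "row"] == panel$coords[, "col"],
               panel$coords[, "row"] * delta / 5, 0)
      }
    },
    single_deme = {
      if (is.null(panel$coords)) stop("single_deme pattern needs grid coordinates")
      ifelse(panel$coords[, "row"] == deme[1] & panel$coords[, "col"] == deme[2],
             delta, 0)
    },
    stop(sprintf("unknown confounding pattern '%s'", pattern))
  )
}

#' Simulate a purely environmental phenotype with a confounding pattern
#'
#' Each GWAS-panel individual gets `y_i = N(0, 1) + c_i`, where the expected
#' environmental effect `c` follows the chosen spatial/population pattern:
#'
#' * `population_shift`: `c = delta` for the second population, 0 otherwise
#'   (the classic mean shift between the two GWAS source populations).
#' * `latitude`: `c = (row - 1) * delta / 5`, a linear gradient with maximum
#'   shift exactly `delta` on a 6-row grid.
#' * `diagonal`: `c = ((row + col) / 2) * delta / 5`, a gradient along the
#'   lattice diagonal (set `diagonal_style = "diagonal_demes_only"` to shift
#'   only demes on the diagonal).
#' * `single_deme`: `c = delta` for the designated deme (default (1, 4)).
#' * `none`: `c = 0`.
#'
#' @param panel The GWAS `genotype_panel`.
#' @param pattern One of the patterns above.
#' @param delta Confounder magnitude in phenotype SD units.
#' @param seed Integer seed.
#' @param diagonal_style `"gradient"` (default) or `"diagonal_demes_only"`.
#' @param deme Length-2 (row, col) of the shifted deme for `single_deme`.
#' @return A `"phenotype_set"` with `u = 0` and `h2 = 0`.
#' @export
environmental_phenotype <- function(panel, pattern, delta, seed = NULL,
                                    diagonal_style = c("gradient",
                                                       "diagonal_demes_only"),
                                    deme = c(1, 4)) {
  stopifnot(inherits(panel, "genotype_panel"))
  diagonal_style <- match.arg(diagonal_style)
  if (!is.null(seed)) set.seed(seed)
  cvec <- confounder_vector(panel, pattern, delta, diagonal_style, deme)
  M <- n_individuals(panel)
  e <- stats::rnorm(M) + cvec
  new_phenotype_set(y = e, u = rep(0, M), e = e, c = cvec, h2 = 0,
                    delta = delta, pattern = pattern)
}

#' Simulate a heritable trait with a controllable true association
#'
#' Selects `n_causal` sites uniformly, draws effects
#' `beta_l ~ N(0, sigma_i^2 [p_l (1 - p_l)]^alpha)` with `p_l` the GWAS-panel
#' allele frequency and `sigma_i^2` solved exactly so the genetic variance
#' `sum_l 2 [p_l(1-p_l)]^(alpha+1) sigma_i^2` equals `h2`. To plant a true
#' polygenic score difference in the test panel, each effect's sign is
#' aligned with the test-panel frequency difference `p_D - p_C` with
#' probability `theta` (`theta = 0.5`: no expected association; `theta = 1`:
#' trait-increasing alleles always at higher frequency in D). The
#' environmental part is `e ~ N(c, 1 - h2)` with `c` the `population_shift`
#' confounder at magnitude `delta`.
#'
#' @param pair A `"panel_pair"` from a tree demography.
#' @param h2 Target heritability in (0, 1).
#' @param n_causal Number of causal sites (`<= L`).
#' @param alpha Frequency-dependence exponent of the effect-size variance.
#' @param theta Sign-alignment probability in `[0.5, 1]`.
#' @param delta Environmental confounder magnitude (added to population B).
#' @param seed Integer seed.
#' @return A `"phenotype_set"` with `causal_sites`, `true_betas` and the
#'   architecture parameters recorded.
#' @export
heritable_phenotype <- function(pair, h2 = 0.3, n_causal = 300, alpha = -0.4,
                                theta = 0.5, delta = 0, seed = NULL) {
  stopifnot(inherits(pair, "panel_pair"), h2 > 0, h2 < 1,
            theta >= 0.5, theta <= 1)
  L <- n_sites(pair$gwas)
  if (n_causal > L) stop("n_causal exceeds the number of sites")
  if (!is.null(seed)) set.seed(seed)

  causal <- sort(sample.int(L, n_causal))
  p <- colMeans(pair$gwas$dosages[, causal, drop = FALSE]) / 2
  het <- p * (1 - p)
  sigma_i2 <- h2 / sum(2 * het^(alpha + 1))
  beta <- stats::rnorm(n_causal, 0, sqrt(sigma_i2 * het^alpha))

  ## align sign(beta) with sign(p_D - p_C) with probability theta
  test_pops <- unique(pair$test$labels)
  ic <- pair$test$labels == test_pops[1]
  id <- pair$test$labels == test_pops[2]
  d <- colMeans(pair$test$dosages[id, causal, drop = FALSE]) / 2 -
       colMeans(pair$test$dosages[ic, causal, drop = FALSE]) / 2
  align <- stats::runif(n_causal) < theta
  nz <- d != 0
  beta[nz] <- abs(beta[nz]) * sign(d[nz]) * ifelse(align[nz], 1, -1)

  u <- as.vector(center_cols(pair$gwas$dosages[, causal, drop = FALSE]) %*% beta)
  M <- n_individuals(pair$gwas)
  cvec <- confounder_vector(pair$gwas, "population_shift", delta)
  e <- stats::rnorm(M, 0, sqrt(1 - h2)) + cvec
  new_phenotype_set(y = u + e, u = u, e = e, c = cvec, h2 = h2, delta = delta,
                    pattern = "population_shift",
                    causal_sites = pair$gwas$site_ids[causal],
                    true_betas = stats::setNames(beta, pair$gwas$site_ids[causal]),
                    theta = theta, alpha = alpha, sigma_i2 = sigma_i2)
}
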