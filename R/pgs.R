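#' Polygenic scores in the test panel
#'
#' `Z_i = sum_{l in sites} beta_l (x_il - mean_l)` with test-panel-centered
#' dosages, re-centered to mean zero exactly after summation. Effects can be
#' estimated (`effect_estimates`) or true (a named numeric vector), which is
#' how the true score `Z` used for `q` is built.
#'
#' @param test A `genotype_panel` (the test panel).
#' @param effects An `"effect_estimates"` object or a numeric vector of
#'   effects named by site id.
#' @param sites Site ids to include (default: all sites with an effect).
#' @return An object of class `"polygenic_scores"`: list with `z` (length N,
#'   mean 0), `sites_used` and `effects_source`.
#' @export
polygenic_scores <- function(test, effects, sites = NULL) {
  stopifnot(inherits(test, "genotype_panel"))
  if (inherits(effects, "effect_estimates")) {
    beta <- stats::setNames(effects$beta_hat, effects$site_id)
    src <- attr(effects, "model_tag")
  } else {
    if (is.null(names(effects))) stop("a bare effect vector must be named by site id")
    beta <- effects
    src <- "true"
  }
  sites <- sites %||% names(beta)[!is.na(beta)]
  miss <- setdiff(sites, test$site_ids)
  if (length(miss)) {
    stop(sprintf("sites not present in the test panel: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  if (anyNA(beta[sites])) stop("NA effect for an included site")
  idx <- match(sites, test$site_ids)
  xc <- center_cols(test$dosages[, idx, drop = FALSE])
  z <- as.vector(xc %*% beta[sites])
  z <- z - mean(z)
  structure(list(z = z, sites_used = sites, effects_source = src),
            class = "polygenic_scores")
}

#' @export
print.polygenic_scores <- function(x, ...) {
  cat(sprintf("polygenic_scores: N=%d individuals, S=%d sites (%s effects)\n",
              length(x$z), length(x$sites_used), x$effects_source))
  invisible(x)
}

#' Polygenic score association statistic
#'
#' The slope of the regression of the (mean-centered) scores on the
#' standardized test vector, `q^ = (1/N) Z^' T`. If true scores are supplied
#' the same statistic is computed from them as `q`; for purely environmental
#' traits the true `q` is identically 0.
#'
#' @param scores A [polygenic_scores()] result built from estimated effects.
#' @param tvec The standardized test vector.
#' @param true_scores Optional [polygenic_scores()] result built from true
#'   effects.
#' @param replicate Optional replicate identifier carried through.
#' @return An object of class `"association_result"`: list with `q_hat`,
#'   `q_true`, `model_tag`, `replicate`.
#' @export
association_statistic <- function(scores, tvec, true_scores = NULL,
                                  replicate = NA_integer_) {
  stopifnot(inherits(scores, "polygenic_scores"), inherits(tvec, "test_vector"),
            length(scores$z) == length(tvec$values))
  N <- length(tvec$values)
  q_hat <- sum(scores$z * tvec$values) / N
  q_true <- if (is.null(true_scores)) 0 else sum(true_scores$z * tvec$values) / N
  structure(list(q_hat = q_hat, q_true = q_true,
                 model_tag = scores$effects_source, replicate = replicate),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result (%s): q_hat=%.4g, q_true=%.4g\n",
              x$model_tag, x$q_hat, x$q_true))
  invisible(x)
}

#' Standardized F4 statistic of a panel pair
#'
#' `(1/L) sum_l (pA_l - pB_l)(pC_l - pD_l) / v_l`, Patterson's four-population
#' statistic standardized by the GWAS-panel genotype variance
#' `v_l = G_l' G_l / M`. It measures drift shared between the GWAS-panel
#' contrast (A vs B) and the test-panel contrast (C vs D): zero when the
#' panels share no internal branch, positive when they do.
#'
#' @param pair A `"panel_pair"`.
#' @param pops Character vector of four group labels in the order A, B
#'   (GWAS panel) then C, D (test panel); defaults to the panels' own label
#'   pairs.
#' @param sites Optional subset of site ids over which to average (e.g. the
#'   ascertained score sites); default all shared sites.
#' @return A single number.
#' @export
f4_standardized <- function(pair, pops = NULL, sites = NULL) {
  stopifnot(inherits(pair, "panel_pair"))
  pops <- pops %||% c(unique(pair$gwas$labels)[1:2], unique(pair$test$labels)[1:2])
  stopifnot(length(pops) == 4)
  ia <- pair$gwas$labels == pops[1]; ib <- pair$gwas$labels == pops[2]
  ic <- pair$test$labels == pops[3]; id <- pair$test$labels == pops[4]
  if (!all(c(sum(ia), sum(ib), sum(ic), sum(id)) > 0)) {
    stop("all four groups must be non-empty")
  }
  idx <- if (is.null(sites)) seq_len(n_sites(pair$gwas)) else {
    m <- match(sites, pair$gwas$site_ids)
    if (anyNA(m)) stop("unknown site id in `sites`")
    m
  }
  g <- pair$gwas$dosages[, idx, drop = FALSE]
  x <- pair$test$dosages[, idx, drop = FALSE]
  pa <- colMeans(g[ia, , drop = FALSE]) / 2
  pb <- colMeans(g[ib, , drop = FALSE]) / 2
  pc <- colMeans(x[ic, , drop = FALSE]) / 2
  pd <- colMeans(x[id, , drop = FALSE]) / 2
  v <- colMeans(center_cols(g)^2)
  if (any(v == 0)) stop("monomorphic GWAS sites; filter first")
  mean((pa - pb) * (pc - pd) / v)
}

#' Predicted bias of the association statistic under a mean confounder shift
#'
#' A confounder shifting the phenotype mean of GWAS population B by
#' `delta_AB` biases each effect estimate by `(delta_AB / 2)(pB - pA)/v`
#' (the factor 1/2 converts the between-group mean shift to a per-allele
#' slope), so for S score sites the expected bias of the association
#' statistic is `delta_AB * S * F4 / 2` with `F4` from [f4_standardized()].
#' The prediction applies to score sites drawn independently of their
#' association signal; ascertaining sites by minimum p-value inflates the
#' realized bias beyond it (see the package vignette).
#'
#' @param delta_AB Confounder magnitude (phenotype SD units).
#' @param S Number of sites in the polygenic score.
#' @param f4 The standardized F4 statistic.
#' @return The predicted `E[q^ - q]`.
#' @export
predicted_bias <- function(delta_AB, S, f4) {
  delta_AB * S * f4 / 2
}

#' Summarize bias across replicates
#'
#' Mean of `q^ - q` over replicate association results with a
#' normal-approximation 95% confidence half-width `1.96 * sd / sqrt(H)`;
#' with a single replicate the CI is reported as missing.
#'
#' @param results A list of `"association_result"` objects (or a numeric
#'   vector of per-replicate `q^ - q`).
#' @param predicted Optional theory value to attach (e.g. from
#'   [predicted_bias()]).
#' @return An object of class `"bias_summary"`: list with `mean_bias`,
#'   `ci95`, `H`, `predicted`.
#' @export
bias_summary <- function(results, predicted = NULL) {
  d <- if (is.numeric(results)) results else {
    vapply(results, function(r) r$q_hat - r$q_true, 0)
  }
  if (!length(d)) stop("no replicates supplied")
  H <- length(d)
  ci <- if (H >= 2) 1.96 * stats::sd(d) / sqrt(H) else NA_real_
  structure(list(mean_bias = mean(d), ci95 = ci, H = H,
                 predicted = predicted),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("bias_summary: mean %.4g +/- %.4g (95%% CI, H=%d)",
              x$mean_bias, x$ci95, x$H))
  if (!is.null(x$predicted)) cat(sprintf("; predicted %.4g", x$predicted))
  cat("\n")
  invisible(x)
}
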