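#' Structure axis objects
#'
#' A structure axis is a length-M vector over GWAS panel individuals
#' describing one direction of population structure: the direct estimator
#' `F^_Gr`, a sample PC, a population PC, or the true test-relevant axis.
#' `values` is the standardized version (mean 0, variance 1 with denominator
#' M), which is the form used as a GWAS covariate; `raw` keeps the
#' pre-standardization estimate.
#'
#' @param raw Numeric vector.
#' @param source One of `"direct_FGr"`, `"sample_pc"`, `"population_pc"`,
#'   `"true_FGr"`, `"custom"`.
#' @param n_sites Number of sites used in estimation (NA when not applicable).
#' @return An object of class `"structure_axis"`.
#' @export
new_structure_axis <- function(raw, source = "custom", n_sites = NA_integer_) {
  if (!all(is.finite(raw))) stop("structure axis entries must be finite")
  degenerate <- isTRUE(all.equal(stats::var(raw), 0)) || stats::var(raw) == 0
  values <- if (degenerate) raw - mean(raw) else standardize_vec(raw)
  structure(list(values = values, raw = raw, source = source,
                 n_sites = n_sites, degenerate = degenerate),
            class = "structure_axis")
}

#' @export
print.structure_axis <- function(x, ...) {
  cat(sprintf("structure_axis (%s): M=%d individuals%s\n", x$source,
              length(x$values),
              if (is.na(x$n_sites)) "" else sprintf(", %d sites", x$n_sites)))
  invisible(x)
}

#' Standardize a test vector
#'
#' The association test statistic is defined for a standardized test vector
#' (mean 0, variance 1, population-style denominator N), so every test axis
#' observed in the test panel -- latitude, a group indicator, a PC -- is
#' passed through this transform first.
#'
#' @param raw Numeric vector of raw test values, one per test-panel
#'   individual; must not be constant.
#' @param kind Label recording what the vector encodes.
#' @return An object of class `"test_vector"` with `values` (standardized) and
#'   `raw`.
#' @examples
#' standardize_test_vector(rep(c(0, 1), each = 5), kind = "population_indicator")
#' @export
standardize_test_vector <- function(raw, kind = c("custom",
                                                  "population_indicator",
                                                  "latitude",
                                                  "deme_indicator")) {
  kind <- match.arg(kind)
  structure(list(values = standardize_vec(raw), raw = raw, kind = kind),
            class = "test_vector")
}

#' @export
print.test_vector <- function(x, ...) {
  cat(sprintf("test_vector (%s): N=%d individuals\n", x$kind, length(x$values)))
  invisible(x)
}

#' Genotype contrasts between the test vector and test-panel genotypes
#'
#' `r_l = (1/N) * X_l' T`, the per-site covariance between the (mean-centered)
#' test-panel dosages and the standardized test vector. The association
#' statistic is the effect-contrast inner product `q = beta' r`, and the
#' contrasts are the ingredient of the direct structure-axis estimator.
#'
#' @param test A `genotype_panel` (the test panel).
#' @param tvec A [standardize_test_vector()] result of matching length.
#' @return An object of class `"genotype_contrasts"`: list with `values`
#'   (length L) and `site_ids`.
#' @export
genotype_contrasts <- function(test, tvec) {
  stopifnot(inherits(test, "genotype_panel"), inherits(tvec, "test_vector"),
            n_individuals(test) == length(tvec$values))
  xc <- center_cols(test$dosages)
  r <- as.vector(crossprod(xc, tvec$values)) / n_individuals(test)
  structure(list(values = r, site_ids = test$site_ids,
                 n_test = n_individuals(test)),
            class = "genotype_contrasts")
}

#' @export
print.genotype_contrasts <- function(x, ...) {
  cat(sprintf("genotype_contrasts: L=%d sites, N=%d test individuals\n",
              length(x$values), x$n_test))
  invisible(x)
}

#' Direct estimator of the test-relevant structure axis
#'
#' For GWAS individual i the estimator averages, over sites, the product of
#' the individual's centered dosage and the test-panel genotype contrast,
#' standardized by the GWAS-panel genotype variance:
#' `F^_Gr[i] = (1/L) sum_l g_il r_l / v_l` with `v_l = G_l' G_l / M` the mean
#' squared centered dosage. Equivalently, entry i is the slope of a
#' regression of individual i's standardized genotypes on the standardized
#' contrasts, so its error shrinks as L and N grow.
#'
#' @param gwas A `genotype_panel` (the GWAS panel).
#' @param r A [genotype_contrasts()] result on the same ordered site set.
#' @param variance `"empirical"` (default; mean squared centered dosage) or
#'   `"expected"` (`2 p (1-p)` from the GWAS sample frequency).
#' @return A `"structure_axis"` with source `"direct_FGr"`.
#' @examples
#' pair <- simulate_tree_panels(tree_demography(), n_per_pop = 50,
#'                              target_sites = 500, seed = 3)
#' tv <- standardize_test_vector(rep(c(0, 1), each = 50), "population_indicator")
#' fgr <- direct_estimator_FGr(pair$gwas, genotype_contrasts(pair$test, tv))
#' @export
direct_estimator_FGr <- function(gwas, r, variance = c("empirical", "expected")) {
  variance <- match.arg(variance)
  stopifnot(inherits(gwas, "genotype_panel"), inherits(r, "genotype_contrasts"))
  if (!identical(gwas$site_ids, r$site_ids)) {
    stop("GWAS panel and contrasts must share the same ordered site set")
  }
  gc <- center_cols(gwas$dosages)
  v <- if (variance == "empirical") {
    colMeans(gc^2)
  } else {
    p <- colMeans(gwas$dosages) / 2
    2 * p * (1 - p)
  }
  if (any(v == 0)) {
    stop("sites with zero genotype variance in the GWAS panel; apply a joint MAF filter first")
  }
  L <- length(v)
  raw <- as.vector(gc %*% (r$values / v)) / L
  new_structure_axis(raw, source = "direct_FGr", n_sites = L)
}

#' Sample principal components of a GWAS panel
#'
#' Left singular vectors of the column-centered, column-variance-standardized
#' dosage matrix, with eigenvalues reported on the scale of `(1/L) X X'` so
#' that the bulk of a structureless panel has mean 1 and the detection
#' threshold of [pc_accuracy_theory()] applies directly. Signs follow the
#' first-nonzero-positive convention.
#'
#' @param gwas A `genotype_panel`.
#' @param k Number of PCs to return (`k <= min(M, L)`).
#' @return A list of `k` `"structure_axis"` objects (source `"sample_pc"`),
#'   with the eigenvalues attached as `attr(, "eigenvalues")` (all
#'   `min(M, L)` of them).
#' @export
sample_pcs <- function(gwas, k) {
  stopifnot(inherits(gwas, "genotype_panel"))
  M <- n_individuals(gwas); L <- n_sites(gwas)
  if (k > min(M, L)) stop("k exceeds min(M, L)")
  gc <- center_cols(gwas$dosages)
  v <- colMeans(gc^2)
  if (any(v == 0)) stop("monomorphic sites in the GWAS panel; filter first")
  gs <- sweep(gc, 2L, sqrt(v), "/", check.margin = FALSE)
  K <- tcrossprod(gs) / L
  eig <- eigen(K, symmetric = TRUE)
  axes <- lapply(seq_len(k), function(j) {
    ax <- new_structure_axis(fix_sign(eig$vectors[, j]), source = "sample_pc",
                             n_sites = L)
    ax$rank <- j
    ax$eigenvalue <- eig$values[j]
    ax
  })
  attr(axes, "eigenvalues") <- eig$values
  axes
}

#' Expected accuracy of a sample PC (random-matrix theory)
#'
#' In the spiked-covariance regime, a sample PC only aligns with its
#' population PC when the population eigenvalue exceeds the detection
#' threshold `1 + sqrt(M/L)`; above it, the squared correlation is
#' `(1 - (M/L)/(lambda-1)^2) / (1 + (M/L)/(lambda-1))`, and below it the two
#' are asymptotically orthogonal.
#'
#' @param lambda_j Population eigenvalue on the scale where the noise bulk has
#'   mean 1.
#' @param M,L GWAS panel size and number of sites.
#' @return Expected squared correlation in `[0, 1]`.
#' @examples
#' pc_accuracy_theory(4, M = 1000, L = 1000)  # 2/3
#' @export
pc_accuracy_theory <- function(lambda_j, M, L) {
  g <- M / L
  out <- ifelse(lambda_j > 1 + sqrt(g),
                (1 - g / (lambda_j - 1)^2) / (1 + g / (lambda_j - 1)),
                0)
  pmin(pmax(out, 0), 1)
}

#' Error of a structure-axis estimate against a known truth
#'
#' `error = 1 - cor(estimate, truth)^2`; sign-invariant, 0 when the estimate
#' spans the true axis and 1 when orthogonal to it.
#'
#' @param estimate,truth `"structure_axis"` objects (or numeric vectors) of
#'   equal length.
#' @return An object of class `"error_estimate"` with elements `error`,
#'   `components` (NULL here), and `bound` (FALSE).
#' @export
axis_error <- function(estimate, truth) {
  e <- if (inherits(estimate, "structure_axis")) estimate$values else standardize_vec(estimate)
  t <- if (inherits(truth, "structure_axis")) truth$values else standardize_vec(truth)
  if (length(e) != length(t)) stop("estimate and truth have different lengths")
  new_error_estimate(1 - stats::cor(e, t)^2)
}

new_error_estimate <- function(error, components = NULL, bound = FALSE,
                               n_replicates = NA_integer_) {
  structure(list(error = error, components = components, bound = bound,
                 n_replicates = n_replicates),
            class = "error_estimate")
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("error_estimate: %s%.4g", if (x$bound) ">= " else "", x$error))
  if (!is.null(x$components)) {
    cat(sprintf("  (within-deme %.4g + deme-mean %.4g)",
                x$components[["within_deme"]], x$components[["deme_mean"]]))
  }
  cat("\n")
  invisible(x)
}

## coerce replicate input (list of axes/vectors or matrix) to an M x H matrix
replicates_matrix <- function(replicates) {
  if (is.matrix(replicates)) return(replicates)
  vecs <- lapply(replicates, function(x) {
    if (inherits(x, "structure_axis")) x$values else as.numeric(x)
  })
  len <- unique(lengths(vecs))
  if (length(len) != 1) stop("replicates must all have the same length")
  do.call(cbind, vecs)
}

#' Error of the direct estimator on the grid, from replicate exchangeability
#'
#' Individuals within a deme are exchangeable, so within a replicate they
#' share the same true axis value; variation of estimates within demes, and
#' variation of deme means across replicates, are both error. The estimate is
#' (mean within-deme variance + across-replicate variance of deme means) over
#' the total variance, each term averaged over demes and replicates.
#'
#' @param replicates An M x H matrix (columns are replicate estimates of
#'   `F^_Gr` for a fixed deme structure), or a list of `"structure_axis"`
#'   objects / numeric vectors.
#' @param deme_labels Length-M deme assignment shared by all replicates.
#' @return An `"error_estimate"`; `components` holds the two numerator shares.
#'   With a single replicate the deme-mean term is unavailable and the result
#'   is flagged as a lower bound.
#' @export
grid_error_direct <- function(replicates, deme_labels) {
  x <- replicates_matrix(replicates)
  H <- ncol(x)
  deme_labels <- as.character(deme_labels)
  stopifnot(length(deme_labels) == nrow(x))
  demes <- split(seq_len(nrow(x)), deme_labels)
  if (any(lengths(demes) < 2)) stop("every deme needs at least two individuals")

  within_h <- vapply(seq_len(H), function(h) {
    mean(vapply(demes, function(ix) stats::var(x[ix, h]), 0))
  }, 0)
  within <- mean(within_h)

  deme_means <- vapply(demes, function(ix) colMeans(x[ix, , drop = FALSE]), numeric(H))
  # deme_means: H x J (or numeric J when H = 1)
  total <- mean(apply(x, 2L, stats::var))
  if (H >= 2) {
    across <- mean(apply(deme_means, 2L, stats::var))
    err <- (within + across) / total
    new_error_estimate(err,
                       components = c(within_deme = within / total,
                                      deme_mean = across / total),
                       bound = FALSE, n_replicates = H)
  } else {
    new_error_estimate(within / total,
                       components = c(within_deme = within / total,
                                      deme_mean = NA_real_),
                       bound = TRUE, n_replicates = H)
  }
}

#' Lower bound on the error of a sample PC on the grid
#'
#' Sample PC ranks need not match population PC ranks across replicates, so
#' only the within-deme variance component is identifiable; the result is a
#' lower bound on the error. PCs are standardized to unit variance, making
#' the within-deme variance directly interpretable as an error fraction.
#'
#' @inheritParams grid_error_direct
#' @return An `"error_estimate"` flagged as a bound.
#' @export
grid_error_pc_bound <- function(replicates, deme_labels) {
  x <- replicates_matrix(replicates)
  x <- apply(x, 2L, standardize_vec)
  deme_labels <- as.character(deme_labels)
  stopifnot(length(deme_labels) == nrow(x))
  demes <- split(seq_len(nrow(x)), deme_labels)
  if (any(lengths(demes) < 2)) stop("every deme needs at least two individuals")
  within_h <- vapply(seq_len(ncol(x)), function(h) {
    mean(vapply(demes, function(ix) stats::var(x[ix, h]), 0))
  }, 0)
  new_error_estimate(mean(within_h),
                     components = c(within_deme = mean(within_h),
                                    deme_mean = NA_real_),
                     bound = TRUE, n_replicates = ncol(x))
}

#' Decompose a structure axis onto principal components
#'
#' Projects an axis onto an orthogonal PC basis: `eta_i = Cov(U_i, axis)` on
#' the standardized scale, with the cumulative variance explained after J PCs
#' given by `sum_{i<=J} eta_i^2 / Var(axis)`. Used to ask how many PCs are
#' needed to capture either a confounder or the test-relevant axis.
#'
#' @param axis A `"structure_axis"` (or numeric vector).
#' @param pcs A list of `"structure_axis"` objects (e.g. from
#'   [sample_pcs()]) or a matrix with orthogonal columns.
#' @return A list with `eta` (projection coefficients) and `cum_r2`
#'   (non-decreasing, bounded by 1).
#' @export
pc_decomposition_of_axis <- function(axis, pcs) {
  a <- if (inherits(axis, "structure_axis")) axis$values else standardize_vec(axis)
  U <- if (is.matrix(pcs)) apply(pcs, 2L, standardize_vec) else replicates_matrix(pcs)
  M <- nrow(U)
  if (length(a) != M) stop("axis and PCs have different lengths")
  gram <- crossprod(U) / M
  if (max(abs(gram - diag(ncol(U)))) > 1e-6) {
    stop("pcs must be orthonormal (orthogonal after standardization)")
  }
  eta <- as.vector(crossprod(U, a)) / M
  cum_r2 <- cumsum(eta^2)  # Var(axis) = 1 on the standardized scale
  list(eta = eta, cum_r2 = pmin(cum_r2, 1))
}
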