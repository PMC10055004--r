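#' Expected relatedness matrix for a tree demography
#'
#' Builds the block matrix of expected relatedness coefficients within and
#' between the GWAS and test panels under the small-drift (linear)
#' approximation: the entry for individuals i and j is the drift time their
#' population lineages share below the root, divided by `2 Ne`, with the root
#' placed at the deepest split (so the two sides of the deepest split share no
#' drift). Individuals from the same population share the entire
#' root-to-present path, sister populations share the internal branch, and
#' cross-clade pairs share nothing.
#'
#' Returned along with the blocks are the mean self-relatedness of the GWAS
#' panel, the standardized cross block `F_tilde_GX = F_GX (1 + F_Gbar)`, and
#' the eigendecomposition of the double-centered within-GWAS block (the
#' "population" PCs).
#'
#' @param model A [tree_demography()].
#' @param n_per_pop Diploids per leaf population in each panel.
#' @return An object of class `"relatedness_f"` with elements `F_XX`, `F_XG`,
#'   `F_GX`, `F_GG`, `F_Gbar`, `F_tilde_GX`, `U` (population PCs of the
#'   centered `F_GG`), `lambda` (their eigenvalues, non-increasing), and the
#'   per-individual population labels of each panel.
#' @examples
#' relF <- theoretical_F(tree_demography(topology = "unconfounded"), 10)
#' max(abs(relF$F_tilde_GX - mean(relF$F_tilde_GX)))  # no cross-panel structure
#' @export
theoretical_F <- function(model, n_per_pop) {
  if (inherits(model, "grid_demography")) {
    stop("theoretical_F is defined for tree demographies only; the grid axis is unknown and handled by exchangeability-based error estimators")
  }
  stopifnot(inherits(model, "tree_demography"), n_per_pop >= 1)
  two_ne <- 2 * model$ne
  t_root <- model$t_deep
  pops <- c("A", "B", "C", "D")
  ## population divergence times under the topology
  sisters <- function(p) {
    for (cl in model$clades) if (p %in% cl) return(setdiff(cl, p))
    stop("unknown population")
  }
  t_div <- matrix(model$t_deep, 4, 4, dimnames = list(pops, pops))
  diag(t_div) <- 0
  for (p in pops) t_div[p, sisters(p)] <- model$t_shallow
  f_pop <- (t_root - t_div) / two_ne

  expand <- function(rows, cols) {
    m <- f_pop[rows, cols, drop = FALSE]
    m[rep(seq_along(rows), each = n_per_pop),
      rep(seq_along(cols), each = n_per_pop), drop = FALSE]
  }
  gw <- model$gwas_pops; ts <- model$test_pops
  F_GG <- expand(gw, gw)
  F_XX <- expand(ts, ts)
  F_GX <- expand(gw, ts)
  F_Gbar <- mean(diag(F_GG))
  F_tilde_GX <- F_GX * (1 + F_Gbar)

  M <- nrow(F_GG)
  H <- diag(M) - matrix(1 / M, M, M)
  eig <- eigen(H %*% F_GG %*% H, symmetric = TRUE)
  U <- apply(eig$vectors, 2L, fix_sign)
  if (min(eig$values) < -1e-10) {
    warning("centered F_GG has a substantially negative eigenvalue")
  }
  structure(list(F_XX = F_XX, F_XG = t(F_GX), F_GX = F_GX, F_GG = F_GG,
                 F_Gbar = F_Gbar, F_tilde_GX = F_tilde_GX,
                 U = U, lambda = eig$values,
                 gwas_labels = rep(gw, each = n_per_pop),
                 test_labels = rep(ts, each = n_per_pop),
                 model = model),
            class = "relatedness_f")
}

#' @export
print.relatedness_f <- function(x, ...) {
  cat(sprintf("relatedness_f: M=%d GWAS x N=%d test individuals; F_Gbar=%.4g\n",
              nrow(x$F_GG), nrow(x$F_XX), x$F_Gbar))
  cat(sprintf("  top centered eigenvalues of F_GG: %s\n",
              paste(signif(utils::head(x$lambda, 3), 4), collapse = ", ")))
  invisible(x)
}

## deterministic eigenvector sign: first coordinate of non-negligible
## magnitude is positive
fix_sign <- function(v) {
  i <- which(abs(v) > 1e-12)
  if (length(i) && v[i[1]] < 0) -v else v
}

#' Population principal components of an expected relatedness block
#'
#' Eigendecomposition of the double-centered `F_GG`: the eigenvectors are the
#' "population" PCs that sample PCs estimate, and the eigenvalues order the
#' amount of expected structure along each axis.
#'
#' @param F_GG Symmetric within-panel relatedness matrix.
#' @return A list with `vectors` (unit-norm columns, first non-zero coordinate
#'   positive) and `values` (non-increasing eigenvalues of the centered
#'   matrix).
#' @export
population_pcs <- function(F_GG) {
  F_GG <- as.matrix(F_GG)
  if (max(abs(F_GG - t(F_GG))) > 1e-8) stop("F_GG must be symmetric")
  M <- nrow(F_GG)
  H <- diag(M) - matrix(1 / M, M, M)
  eig <- eigen(H %*% F_GG %*% H, symmetric = TRUE)
  list(vectors = apply(eig$vectors, 2L, fix_sign), values = eig$values)
}

#' True test-relevant structure axis from the theoretical relatedness
#'
#' The single axis of GWAS-panel structure that must be controlled to protect
#' a given association test is the standardized cross-panel relatedness
#' projected through the test vector, `F_tilde_GX %*% T`. For the confounded
#' tree topology this is the indicator of which side of the deepest split each
#' GWAS individual falls on; for the unconfounded topology it is a constant
#' (no axis needs protecting) and an error is raised since it cannot be
#' standardized.
#'
#' @param relF A [theoretical_F()] result.
#' @param tvec A [standardize_test_vector()] result (length-N).
#' @return A `"structure_axis"` with source `"true_FGr"`.
#' @export
true_structure_axis <- function(relF, tvec) {
  stopifnot(inherits(relF, "relatedness_f"), inherits(tvec, "test_vector"))
  raw <- as.vector(relF$F_tilde_GX %*% tvec$values)
  new_structure_axis(raw, source = "true_FGr", n_sites = NA_integer_)
}
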