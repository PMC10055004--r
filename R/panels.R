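#' Construct a genotype panel
#'
#' A genotype panel holds a diploid dosage matrix (individuals x sites, values
#' in 0/1/2) together with individual labels (population or deme of origin,
#' with lattice coordinates for grid panels), stable site identifiers, and
#' optionally the per-site ancestral frequencies when these are known from
#' simulation.
#'
#' @param dosages Integer matrix, individuals x sites, values in \{0, 1, 2\}.
#' @param labels Character or factor vector of population/deme labels, one per
#'   individual.
#' @param site_ids Unique site identifiers (default `"s1" ... "sL"`).
#' @param coords Optional two-column matrix of (row, col) deme coordinates for
#'   grid panels.
#' @param ancestral_freqs Optional per-site ancestral allele frequencies.
#' @return An object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(dosages, labels,
                           site_ids = paste0("s", seq_len(ncol(dosages))),
                           coords = NULL, ancestral_freqs = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0, 1, 2))) {
    stop("dosages must be diploid allele counts in {0, 1, 2}")
  }
  if (length(labels) != nrow(dosages)) {
    stop("labels must have one entry per individual (row)")
  }
  if (anyDuplicated(site_ids) || length(site_ids) != ncol(dosages)) {
    stop("site_ids must be unique and match the number of sites")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == nrow(dosages), ncol(coords) == 2)
    colnames(coords) <- c("row", "col")
  }
  if (!is.null(ancestral_freqs)) {
    stopifnot(length(ancestral_freqs) == ncol(dosages))
  }
  structure(list(dosages = dosages, labels = as.character(labels),
                 site_ids = as.character(site_ids), coords = coords,
                 ancestral_freqs = ancestral_freqs),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d sites; labels: %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

#' Number of individuals / sites in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosages)

#' @rdname n_individuals
#' @export
n_sites <- function(panel) ncol(panel$dosages)

#' Bundle a GWAS and a test panel sharing one site set
#'
#' Used directly for real-data input (e.g. panels read with [read_vcf()] or
#' [read_dosage_table()]); the simulators return the same structure. Both
#' panels must carry an identical, identically ordered site set, and with
#' `check_maf = TRUE` every site is checked for minor allele frequency at
#' least `maf_min` in both panels.
#'
#' @param gwas,test `genotype_panel` objects with identical `site_ids`.
#' @param maf_min The joint MAF threshold the shared site set satisfies.
#' @param seed Optional seed recorded for provenance.
#' @param demography Optional demography object recorded for provenance.
#' @param check_maf Verify the joint MAF filter on construction.
#' @return An object of class `"panel_pair"`.
#' @export
panel_pair <- function(gwas, test, maf_min = 0.01, seed = NULL,
                       demography = NULL, check_maf = FALSE) {
  if (check_maf) {
    ok <- joint_maf_keep(gwas$dosages, test$dosages, maf_min)
    if (!all(ok)) {
      stop(sprintf("%d site(s) fail the MAF >= %g filter in one of the panels",
                   sum(!ok), maf_min))
    }
  }
  new_panel_pair(gwas, test, maf_min, seed, demography)
}

new_panel_pair <- function(gwas, test, maf_min, seed, demography) {
  stopifnot(identical(gwas$site_ids, test$site_ids))
  structure(list(gwas = gwas, test = test, maf_min = maf_min, seed = seed,
                 demography = demography),
            class = "panel_pair")
}

#' @export
print.panel_pair <- function(x, ...) {
  cat(sprintf("panel_pair: M=%d GWAS / N=%d test individuals, L=%d shared sites (MAF >= %g in both)\n",
              n_individuals(x$gwas), n_individuals(x$test),
              n_sites(x$gwas), x$maf_min))
  invisible(x)
}

## sample a dosage matrix of n diploids given per-site frequencies p
draw_dosages <- function(p, n) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

## joint MAF filter on sample frequencies of both panels
joint_maf_keep <- function(gwas_dosages, test_dosages, maf_min) {
  fg <- colMeans(gwas_dosages) / 2
  fx <- colMeans(test_dosages) / 2
  pmin(fg, 1 - fg) >= maf_min & pmin(fx, 1 - fx) >= maf_min
}

#' Simulate a GWAS/test panel pair under a tree demography
#'
#' Sites are mutually independent: each site's population frequencies are
#' drawn from a 1/x ancestral spectrum and then drift down the tree, with the
#' per-branch drift matched to the diffusion expectation
#' `1 - exp(-t/(2 Ne))`; individual dosages are binomial draws given the
#' population frequency. A surplus of sites (3x the target, with one retry)
#' is simulated and filtered so that every retained site has minor allele
#' frequency at least `maf_min` in *both* panels; the first `target_sites`
#' passing sites are kept.
#'
#' @param model A [tree_demography()].
#' @param n_per_pop Diploids sampled per leaf population (the GWAS panel has
#'   `2 * n_per_pop` individuals, as does the test panel).
#' @param target_sites Number of sites to retain after the joint MAF filter.
#' @param maf_min Minor allele frequency threshold applied to both panels.
#' @param seed Integer seed; the same seed reproduces the pair exactly.
#' @return A `"panel_pair"` with `$gwas` and `$test` panels sharing an
#'   identical ordered site set.
#' @examples
#' pair <- simulate_tree_panels(tree_demography(), n_per_pop = 50,
#'                              target_sites = 200, seed = 1)
#' pair
#' @export
simulate_tree_panels <- function(model, n_per_pop, target_sites,
                                 maf_min = 0.01, seed = NULL) {
  stopifnot(inherits(model, "tree_demography"), n_per_pop >= 2,
            target_sites >= 1, maf_min >= 0, maf_min < 0.5)
  if (!is.null(seed)) set.seed(seed)
  two_ne <- 2 * model$ne
  f_internal <- 1 - exp(-(model$t_deep - model$t_shallow) / two_ne)
  f_leaf <- 1 - exp(-model$t_shallow / two_ne)

  sim_batch <- function(n_sites) {
    a <- rsfs(n_sites)
    clade1 <- bn_drift(a, f_internal)
    clade2 <- bn_drift(a, f_internal)
    p <- list()
    p[[model$clades[[1]][1]]] <- bn_drift(clade1, f_leaf)
    p[[model$clades[[1]][2]]] <- bn_drift(clade1, f_leaf)
    p[[model$clades[[2]][1]]] <- bn_drift(clade2, f_leaf)
    p[[model$clades[[2]][2]]] <- bn_drift(clade2, f_leaf)
    gwas <- rbind(draw_dosages(p$A, n_per_pop), draw_dosages(p$B, n_per_pop))
    test <- rbind(draw_dosages(p$C, n_per_pop), draw_dosages(p$D, n_per_pop))
    keep <- joint_maf_keep(gwas, test, maf_min)
    list(gwas = gwas[, keep, drop = FALSE], test = test[, keep, drop = FALSE],
         anc = a[keep])
  }

  surplus <- 3L * target_sites
  batch <- sim_batch(surplus)
  if (ncol(batch$gwas) < target_sites) {  # one retry with a fresh surplus
    extra <- sim_batch(surplus)
    batch <- list(gwas = cbind(batch$gwas, extra$gwas),
                  test = cbind(batch$test, extra$test),
                  anc = c(batch$anc, extra$anc))
  }
  if (ncol(batch$gwas) < target_sites) {
    stop(sprintf(paste("only %d of the requested %d sites passed the joint",
                       "MAF >= %g filter after simulating %d surplus sites;",
                       "lower maf_min or target_sites"),
                 ncol(batch$gwas), target_sites, maf_min, 2L * surplus))
  }
  sel <- seq_len(target_sites)
  ids <- paste0("s", sel)
  gwas_labels <- rep(model$gwas_pops, each = n_per_pop)
  test_labels <- rep(model$test_pops, each = n_per_pop)
  new_panel_pair(
    genotype_panel(batch$gwas[, sel, drop = FALSE], gwas_labels, ids,
                   ancestral_freqs = batch$anc[sel]),
    genotype_panel(batch$test[, sel, drop = FALSE], test_labels, ids,
                   ancestral_freqs = batch$anc[sel]),
    maf_min = maf_min, seed = seed, demography = model)
}

#' Simulate a GWAS/test panel pair under a stepping-stone grid
#'
#' Deme allele frequencies are drawn from the migration-drift equilibrium of
#' the lattice: each independent site gets an ancestral frequency `a` from a
#' 1/x spectrum and centered deme deviations from the equilibrium Gaussian
#' with covariance `a(1-a) C`, where `C` solves the linearized drift-migration
#' recursion (see [grid_demography()]). Half the sampled individuals in every
#' deme go to the GWAS panel and half to the test panel, with (row, col)
#' coordinates recorded. The joint MAF filter works as in
#' [simulate_tree_panels()].
#'
#' @inheritParams simulate_tree_panels
#' @param model A [grid_demography()].
#' @return A `"panel_pair"`; each panel has `samples_per_deme / 2` individuals
#'   per deme and a `$coords` matrix.
#' @export
simulate_grid_panels <- function(model, target_sites, maf_min = 0.01,
                                 seed = NULL) {
  stopifnot(inherits(model, "grid_demography"), target_sites >= 1,
            maf_min >= 0, maf_min < 0.5)
  if (!is.null(seed)) set.seed(seed)
  eq <- grid_equilibrium_cov(model)
  D <- model$rows * model$cols
  half <- model$samples_per_deme %/% 2L

  sim_batch <- function(n_sites) {
    a <- rsfs(n_sites)
    z <- matrix(stats::rnorm(D * n_sites), D, n_sites)
    delta <- eq$factor %*% z
    p <- sweep(delta, 2L, sqrt(a * (1 - a)), "*")
    p <- sweep(p, 2L, a, "+")
    p[p < 0] <- 0
    p[p > 1] <- 1
    gwas <- matrix(0L, D * half, n_sites)
    test <- matrix(0L, D * half, n_sites)
    for (d in seq_len(D)) {
      rows <- ((d - 1L) * half + 1L):(d * half)
      gwas[rows, ] <- draw_dosages(p[d, ], half)
      test[rows, ] <- draw_dosages(p[d, ], half)
    }
    keep <- joint_maf_keep(gwas, test, maf_min)
    list(gwas = gwas[, keep, drop = FALSE], test = test[, keep, drop = FALSE],
         anc = a[keep])
  }

  surplus <- 3L * target_sites
  batch <- sim_batch(surplus)
  if (ncol(batch$gwas) < target_sites) {
    extra <- sim_batch(surplus)
    batch <- list(gwas = cbind(batch$gwas, extra$gwas),
                  test = cbind(batch$test, extra$test),
                  anc = c(batch$anc, extra$anc))
  }
  if (ncol(batch$gwas) < target_sites) {
    stop(sprintf(paste("only %d of the requested %d sites passed the joint",
                       "MAF >= %g filter after simulating %d surplus sites"),
                 ncol(batch$gwas), target_sites, maf_min, 2L * surplus))
  }
  sel <- seq_len(target_sites)
  ids <- paste0("s", sel)
  deme_row <- rep(rep(seq_len(model$rows), times = model$cols), each = half)
  deme_col <- rep(rep(seq_len(model$cols), each = model$rows), each = half)
  labels <- sprintf("deme_%d_%d", deme_row, deme_col)
  coords <- cbind(row = deme_row, col = deme_col)
  new_panel_pair(
    genotype_panel(batch$gwas[, sel, drop = FALSE], labels, ids,
                   coords = coords, ancestral_freqs = batch$anc[sel]),
    genotype_panel(batch$test[, sel, drop = FALSE], labels, ids,
                   coords = coords, ancestral_freqs = batch$anc[sel]),
    maf_min = maf_min, seed = seed, demography = model)
}

#' Hudson's F_ST between two groups of a panel
#'
#' Per-site Hudson estimator with the finite-sample correction
#' `p(1-p)/(n_chromosomes - 1)` in the numerator, combined across sites as a
#' ratio of averages (sum of numerators over sum of denominators), which is
#' the recommended way to average F_ST over loci.
#'
#' @param panel A `genotype_panel`.
#' @param group_a,group_b Either label values (matched against
#'   `panel$labels`) or integer/logical index vectors selecting individuals.
#' @return A single F_ST value.
#' @examples
#' pair <- simulate_tree_panels(tree_demography(), n_per_pop = 100,
#'                              target_sites = 2000, seed = 7)
#' hudson_fst(pair$gwas, "A", "B")
#' @export
hudson_fst <- function(panel, group_a, group_b) {
  stopifnot(inherits(panel, "genotype_panel"))
  resolve <- function(g) {
    if (is.character(g)) return(which(panel$labels %in% g))
    if (is.logical(g)) return(which(g))
    as.integer(g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least two individuals")
  }
  n1 <- 2 * length(ia); n2 <- 2 * length(ib)
  p1 <- colMeans(panel$dosages[ia, , drop = FALSE]) / 2
  p2 <- colMeans(panel$dosages[ib, , drop = FALSE]) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) stop("all sites are monomorphic in both groups; F_ST undefined")
  sum(num) / sum(den)
}
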