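#' Four-population tree demography
#'
#' A balanced two-split phylogeny relating four present-day populations
#' A, B, C and D, all with a constant diploid effective size. The GWAS panel
#' is an equal mixture of A and B; the test panel an equal mixture of C and D.
#' The `topology` controls how much population structure the two panels share:
#'
#' * `"confounded"`: A is sister to C and B is sister to D, so the GWAS-panel
#'   split (A vs B) shares the internal branches with the test-panel split
#'   (C vs D) and the association test is confounded by stratification.
#' * `"unconfounded"`: A is sister to B and C to D; the two panels' internal
#'   structure does not overlap.
#'
#' Setting `t_shallow = 0` collapses each sister pair into a single
#' population, giving the two-population "complete overlap" model in which
#' both panels are drawn 50:50 from the two sides of a single split.
#'
#' @param ne Diploid effective population size, constant across the tree.
#' @param t_deep Generations before present of the deeper split.
#' @param t_shallow Generations before present of the shallower splits
#'   (`0 <= t_shallow <= t_deep`).
#' @param topology `"confounded"` or `"unconfounded"` (see Details).
#' @return An object of class `"tree_demography"`.
#' @examples
#' tree_demography(ne = 10000, t_deep = 200, t_shallow = 100)
#' @export
tree_demography <- function(ne = 10000, t_deep = 200, t_shallow = 100,
                            topology = c("confounded", "unconfounded")) {
  topology <- match.arg(topology)
  stopifnot(ne > 0, t_deep >= t_shallow, t_shallow >= 0)
  clades <- if (topology == "confounded") {
    list(c("A", "C"), c("B", "D"))
  } else {
    list(c("A", "B"), c("C", "D"))
  }
  structure(list(ne = ne, t_deep = t_deep, t_shallow = t_shallow,
                 topology = topology, clades = clades,
                 gwas_pops = c("A", "B"), test_pops = c("C", "D")),
            class = "tree_demography")
}

#' @export
print.tree_demography <- function(x, ...) {
  cat(sprintf("tree_demography: Ne=%g, splits %g/%g generations, %s topology\n",
              x$ne, x$t_deep, x$t_shallow, x$topology))
  cat(sprintf("  clades: (%s) (%s); GWAS = A+B, test = C+D\n",
              paste(x$clades[[1]], collapse = ","),
              paste(x$clades[[2]], collapse = ",")))
  invisible(x)
}

#' Stepping-stone grid demography
#'
#' A `rows` x `cols` lattice of demes exchanging migrants with their
#' 4-neighbours at a symmetric per-generation rate `m`, at migration-drift
#' equilibrium ("structure extends infinitely far back"). Sampled individuals
#' are split evenly between the GWAS and test panels within every deme, so
#' both panels carry the full spatial structure.
#'
#' @param rows,cols Lattice dimensions.
#' @param migration_rate Per-generation migration rate to each adjacent deme,
#'   in `(0, 0.5]`.
#' @param deme_size Diploid effective size of each deme.
#' @param samples_per_deme Diploids sampled per deme (split 50:50 across the
#'   two panels, so it must be even).
#' @return An object of class `"grid_demography"`.
#' @examples
#' grid_demography()  # the 6x6, m = 0.01 default
#' @export
grid_demography <- function(rows = 6, cols = 6, migration_rate = 0.01,
                            deme_size = 1000, samples_per_deme = 80) {
  stopifnot(rows >= 2 || cols >= 2, migration_rate > 0, migration_rate <= 0.5,
            deme_size > 0, samples_per_deme >= 2,
            (rows * cols * samples_per_deme) %% 2 == 0,
            samples_per_deme %% 2 == 0)
  structure(list(rows = rows, cols = cols, migration_rate = migration_rate,
                 deme_size = deme_size, samples_per_deme = samples_per_deme),
            class = "grid_demography")
}

#' @export
print.grid_demography <- function(x, ...) {
  cat(sprintf("grid_demography: %dx%d lattice, m=%g, deme Ne=%g, %d sampled/deme\n",
              x$rows, x$cols, x$migration_rate, x$deme_size, x$samples_per_deme))
  invisible(x)
}

## --- internal: equilibrium allele-frequency covariance on the grid ---------
##
## Linearized drift-migration recursion for centered deme frequency deviations
## delta (in units of a(1-a)):
##   delta' = W A delta + noise,  Var(noise_d) = (1 - C_dd) / (2 N_deme)
## with A the (doubly stochastic) migration matrix and W the projection that
## removes the grand mean (whose variance grows without bound and is absorbed
## into the ancestral frequency draw). The equilibrium covariance C solves a
## discrete Lyapunov equation, found here by fixed-point iteration.
grid_equilibrium_cov <- function(model, tol = 1e-11, max_iter = 60000L) {
  key <- paste(model$rows, model$cols, model$migration_rate, model$deme_size,
               sep = "_")
  cached <- .strataxis_cache[[key]]
  if (!is.null(cached)) return(cached)
  D <- model$rows * model$cols
  idx <- function(r, c) (c - 1L) * model$rows + r
  A <- diag(D)
  m <- model$migration_rate
  for (r in seq_len(model$rows)) for (c in seq_len(model$cols)) {
    nb <- list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    for (n in nb) {
      if (n[1] >= 1 && n[1] <= model$rows && n[2] >= 1 && n[2] <= model$cols) {
        A[idx(r, c), idx(n[1], n[2])] <- m
        A[idx(r, c), idx(r, c)] <- A[idx(r, c), idx(r, c)] - m
      }
    }
  }
  W <- diag(D) - matrix(1 / D, D, D)
  C <- matrix(0, D, D)
  twoN <- 2 * model$deme_size
  for (i in seq_len(max_iter)) {
    noise <- W %*% diag((1 - diag(C)) / twoN) %*% W
    Cn <- W %*% (A %*% C %*% t(A)) %*% W + noise
    if (max(abs(Cn - C)) < tol) { C <- Cn; break }
    C <- Cn
  }
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  fac <- eig$vectors %*% diag(sqrt(vals))
  out <- list(cov = C, factor = fac, migration = A)
  assign(key, out, envir = .strataxis_cache)
  out
}

.strataxis_cache <- new.env(parent = emptyenv())
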