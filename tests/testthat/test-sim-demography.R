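test_that("tree panel simulation enforces the joint MAF filter, site count and determinism", {
  model <- tree_demography(ne = 10000, t_deep = 200, t_shallow = 100)
  pair <- simulate_tree_panels(model, n_per_pop = 60, target_sites = 500,
                               maf_min = 0.01, seed = 42)
  expect_equal(n_sites(pair$gwas), 500)
  expect_equal(n_individuals(pair$gwas), 120)
  for (panel in list(pair$gwas, pair$test)) {
    f <- colMeans(panel$dosages) / 2
    expect_true(all(pmin(f, 1 - f) >= 0.01))
    expect_true(all(panel$dosages %in% 0:2))
  }
  expect_identical(pair$gwas$labels, rep(c("A", "B"), each = 60))
  pair2 <- simulate_tree_panels(model, n_per_pop = 60, target_sites = 500,
                                maf_min = 0.01, seed = 42)
  expect_identical(pair$gwas$dosages, pair2$gwas$dosages)
  expect_identical(pair$test$dosages, pair2$test$dosages)
  ## an unattainable filter fails informatively
  expect_error(simulate_tree_panels(model, n_per_pop = 10, target_sites = 500,
                                    maf_min = 0.45, seed = 1),
               "MAF")
})

test_that("grid panels place half the sampled individuals per deme in each panel, deterministically", {
  model <- grid_demography(rows = 3, cols = 3, migration_rate = 0.02,
                           deme_size = 500, samples_per_deme = 8)
  pair <- simulate_grid_panels(model, target_sites = 300, seed = 7)
  expect_equal(n_sites(pair$gwas), 300)
  for (panel in list(pair$gwas, pair$test)) {
    expect_equal(unname(table(panel$labels)), rep(4L, 9), ignore_attr = TRUE)
    expect_false(is.null(panel$coords))
    f <- colMeans(panel$dosages) / 2
    expect_true(all(pmin(f, 1 - f) >= 0.01))
  }
  pair2 <- simulate_grid_panels(model, target_sites = 300, seed = 7)
  expect_identical(pair$gwas$dosages, pair2$gwas$dosages)
})

test_that("Hudson F_ST hits its deterministic endpoints and matches the count-based oracle", {
  ## alternate fixation at every site -> exactly 1
  dos <- rbind(matrix(2L, 4, 10), matrix(0L, 4, 10))
  panel <- make_panel(dos, rep(c("a", "b"), each = 4))
  expect_equal(hudson_fst(panel, "a", "b"), 1)
  ## identical underlying frequencies -> near 0 over many sites
  set.seed(1)
  p <- runif(4000, 0.2, 0.8)
  panel2 <- make_panel(rbind(draw2 <- matrix(rbinom(50 * 4000, 2, rep(p, each = 50)), 50),
                             matrix(rbinom(50 * 4000, 2, rep(p, each = 50)), 50)),
                       rep(c("a", "b"), each = 50))
  expect_lt(abs(hudson_fst(panel2, "a", "b")), 0.002)
  ## agrees exactly with an independently coded estimator
  set.seed(2)
  dos3 <- matrix(rbinom(20 * 200, 2, 0.4), 20)
  panel3 <- make_panel(dos3, rep(c("a", "b"), each = 10))
  f1 <- colMeans(dos3[1:10, ]) / 2; f2 <- colMeans(dos3[11:20, ]) / 2
  expect_equal(hudson_fst(panel3, "a", "b"),
               oracle_hudson_fst(f1, f2, 20, 20), tolerance = 1e-12)
  expect_error(hudson_fst(make_panel(matrix(2L, 4, 3), rep(c("a", "b"), each = 2)),
                          "a", "b"), "monomorphic")
})

test_that("two-population drift matches the closed form and a forward Wright-Fisher oracle", {
  ne <- 2000; t <- 100
  expected <- 1 - exp(-t / (2 * ne))
  model <- tree_demography(ne = ne, t_deep = t, t_shallow = 0)
  pair <- simulate_tree_panels(model, n_per_pop = 200, target_sites = 10000,
                               seed = 5)
  fst_pkg <- hudson_fst(pair$gwas, "A", "B")
  expect_gt(fst_pkg, 0.8 * expected)
  expect_lt(fst_pkg, 1.2 * expected)
  fst_wf <- oracle_wf_fst(t, ne, n_sites = 6000, n_diploid = 200, seed = 6)
  expect_gt(fst_wf, 0.8 * expected)
  expect_lt(fst_wf, 1.2 * expected)
  ## panmixia: no drift separation
  pair0 <- simulate_tree_panels(tree_demography(ne = ne, t_deep = 0,
                                                t_shallow = 0),
                                n_per_pop = 100, target_sites = 4000, seed = 8)
  expect_lt(abs(hudson_fst(pair0$gwas, "A", "B")), 0.002)
})

test_that("near-panmictic migration erases grid structure", {
  model <- grid_demography(rows = 2, cols = 2, migration_rate = 0.5,
                           deme_size = 500, samples_per_deme = 40)
  pair <- simulate_grid_panels(model, target_sites = 2000, seed = 9)
  fst <- hudson_fst(pair$gwas, "deme_1_1", "deme_2_2")
  expect_lt(abs(fst), 0.005)
})

test_that("theoretical F has the advertised block structure, PSD spectrum and cross-panel behaviour", {
  ## confounded: sister pairs span the panels, one structure axis separates A from B
  relF <- theoretical_F(tree_demography(10000, 200, 100, "confounded"), 5)
  expect_equal(dim(relF$F_GG), c(10, 10))
  ## within-population blocks share the full root-to-present drift
  expect_equal(relF$F_GG[1, 2], 200 / 20000)
  ## A and B meet only at the root: no shared drift below it
  expect_equal(relF$F_GG[1, 6], 0)
  ## sister cross-panel entries share the internal branch
  expect_equal(relF$F_GX[1, 1], (200 - 100) / 20000)
  expect_equal(relF$F_GX[1, 6], 0)
  expect_equal(relF$F_tilde_GX, relF$F_GX * (1 + relF$F_Gbar))
  expect_true(min(relF$lambda) >= -1e-10)
  ## exactly one non-trivial centered eigenvector, the A-vs-B indicator
  expect_equal(sum(relF$lambda > 1e-12), 1)
  expect_equal(abs(relF$U[, 1]), rep(1 / sqrt(10), 10))
  expect_equal(relF$U[1, 1], -relF$U[6, 1])
  ## unconfounded: constant cross block, so the centered axis vanishes
  relU <- theoretical_F(tree_demography(10000, 200, 100, "unconfounded"), 5)
  expect_equal(max(abs(relU$F_tilde_GX - mean(relU$F_tilde_GX))), 0)
  tv <- balanced_t(10)
  expect_true(true_structure_axis(relU, tv)$degenerate)
  ax <- true_structure_axis(relF, tv)
  expect_equal(abs(cor(ax$values, rep(c(1, 0), each = 5))), 1)
  expect_error(theoretical_F(grid_demography(), 5), "tree")
})

test_that("population PCs of a two-block relatedness matrix match the analytic indicator axis", {
  c1 <- 0.01
  F_GG <- matrix(0, 10, 10)
  F_GG[1:5, 1:5] <- c1
  F_GG[6:10, 6:10] <- c1
  pcs <- population_pcs(F_GG)
  expect_equal(abs(pcs$vectors[, 1]), rep(1 / sqrt(10), 10))
  expect_equal(pcs$values[1], c1 * 5)
  expect_lt(pcs$values[2], 1e-12)
  ## constant matrix: no structure PCs at all
  pcs0 <- population_pcs(matrix(0.3, 8, 8))
  expect_true(all(abs(pcs0$values) < 1e-12))
  expect_error(population_pcs(matrix(rnorm(16), 4)), "symmetric")
})
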