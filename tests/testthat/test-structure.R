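test_that("test-vector standardization is exact, idempotent, and rejects constants", {
  tv <- standardize_test_vector(c(0, 0, 1, 1), "population_indicator")
  expect_equal(mean(tv$values), 0, tolerance = 1e-12)
  expect_equal(mean(tv$values^2), 1, tolerance = 1e-12)
  expect_equal(tv$values, c(-1, -1, 1, 1))
  ## idempotence
  tv2 <- standardize_test_vector(tv$values)
  expect_equal(tv2$values, tv$values, tolerance = 1e-14)
  ## affine transform of latitude keeps correlation 1
  lat <- rep(0:5, each = 4)
  tvl <- standardize_test_vector(lat, "latitude")
  expect_equal(cor(tvl$values, lat), 1)
  expect_error(standardize_test_vector(rep(3, 5)), "constant")
})

test_that("genotype contrasts equal the direct summation oracle", {
  ## monomorphic site -> exactly 0
  dos <- cbind(rep(1L, 8), c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L),
               c(2L, 1L, 2L, 0L, 1L, 0L, 1L, 1L))
  panel <- make_panel(dos, rep(c("c", "d"), each = 4))
  tv <- balanced_t(8)
  r <- genotype_contrasts(panel, tv)
  expect_equal(r$values[1], 0)
  ## balanced +/-1 vector: r = (m1 - m2) / 2 for group dosage means m1, m2
  m1 <- colMeans(dos[1:4, ]); m2 <- colMeans(dos[5:8, ])
  expect_equal(r$values, (m1 - m2) / 2, tolerance = 1e-12)
  ## literal summation oracle
  oracle <- apply(sweep(dos, 2, colMeans(dos)), 2,
                  function(x) sum(x * tv$values)) / 8
  expect_equal(r$values, oracle, tolerance = 1e-12)
})

test_that("contrasts under an independent test vector match the sampling-variance formula", {
  set.seed(51)
  N <- 400; L <- 800
  dos <- matrix(rbinom(N * L, 2, rep(runif(L, 0.1, 0.9), each = N)), N)
  panel <- make_panel(dos, rep("x", N))
  tv <- standardize_test_vector(sample(rep(c(1, -1), each = N / 2)))
  r <- genotype_contrasts(panel, tv)
  expect_lt(abs(mean(r$values)), 0.01)
  vars <- colMeans(sweep(dos, 2, colMeans(dos))^2)
  expect_lt(abs(mean(r$values^2) / (mean(vars) / N) - 1), 0.2)
})

test_that("the direct estimator obeys its exact single-site and invariance properties", {
  ## L = 1, centered dosages (1, -1), v = 1, r = 0.5 -> raw axis (0.5, -0.5)
  panel <- make_panel(cbind(c(2L, 0L)), c("a", "b"))
  r <- structure(list(values = 0.5, site_ids = "s1", n_test = 2),
                 class = "genotype_contrasts")
  fgr <- direct_estimator_FGr(panel, r)
  expect_equal(fgr$raw, c(0.5, -0.5))
  ## r = 0 -> zero (degenerate) axis
  r0 <- structure(list(values = 0, site_ids = "s1", n_test = 2),
                  class = "genotype_contrasts")
  fgr0 <- direct_estimator_FGr(panel, r0)
  expect_true(fgr0$degenerate)
  expect_equal(fgr0$raw, c(0, 0))
  ## duplicating every site leaves the estimate unchanged
  set.seed(52)
  dos <- matrix(rbinom(40 * 30, 2, 0.4), 40)
  pan <- make_panel(dos, rep(c("a", "b"), each = 20))
  rv <- rnorm(30) / 10
  rr <- structure(list(values = rv, site_ids = pan$site_ids, n_test = 40),
                  class = "genotype_contrasts")
  f1 <- direct_estimator_FGr(pan, rr)
  pan2 <- make_panel(cbind(dos, dos), rep(c("a", "b"), each = 20),
                     site_ids = paste0("s", 1:60))
  rr2 <- structure(list(values = c(rv, rv), site_ids = pan2$site_ids,
                        n_test = 40), class = "genotype_contrasts")
  f2 <- direct_estimator_FGr(pan2, rr2)
  expect_equal(f1$raw, f2$raw, tolerance = 1e-12)
  ## mismatched site sets are refused
  expect_error(direct_estimator_FGr(pan2, rr), "site set")
})

test_that("the direct estimator converges on the true axis under complete overlap", {
  model <- tree_demography(ne = 10000, t_deep = 200, t_shallow = 0)
  pair <- simulate_tree_panels(model, n_per_pop = 500, target_sites = 20000,
                               seed = 53)
  tv <- standardize_test_vector(as.numeric(pair$test$labels == "D"),
                                "population_indicator")
  fgr <- direct_estimator_FGr(pair$gwas, genotype_contrasts(pair$test, tv))
  truth <- new_structure_axis(as.numeric(pair$gwas$labels == "B"),
                              source = "true_FGr")
  expect_lt(axis_error(fgr, truth)$error, 0.05)
})

test_that("sample PCs are orthonormal and match a dense decomposition on a duplicate-pair toy", {
  dos <- rbind(c(0L, 2L, 1L, 0L, 2L), c(0L, 2L, 1L, 0L, 2L),
               c(2L, 0L, 1L, 2L, 0L), c(2L, 0L, 1L, 1L, 0L))
  dos <- dos[, apply(dos, 2, var) > 0]
  panel <- make_panel(dos, c("p1", "p1", "p2", "p2"))
  pcs <- sample_pcs(panel, 3)
  U <- vapply(pcs, function(a) a$raw, numeric(4))
  expect_equal(crossprod(U), diag(3), tolerance = 1e-10)
  ## PC1 separates the duplicate pair from the others
  expect_gt(abs(cor(pcs[[1]]$values, c(1, 1, -1, -1))), 0.99)
  ## matches a brute-force eigendecomposition of the standardized covariance
  gc <- sweep(dos, 2, colMeans(dos))
  gs <- sweep(gc, 2, sqrt(colMeans(gc^2)), "/")
  eo <- eigen(tcrossprod(gs) / ncol(gs), symmetric = TRUE)
  expect_equal(abs(U[, 1]), abs(eo$vectors[, 1]), tolerance = 1e-10)
  expect_equal(pcs[[1]]$eigenvalue, eo$values[1], tolerance = 1e-10)
  expect_error(sample_pcs(panel, 10), "k exceeds")
})

test_that("a strongly structured panel puts its population axis in PC1", {
  model <- tree_demography(ne = 10000, t_deep = 200, t_shallow = 0)
  pair <- simulate_tree_panels(model, n_per_pop = 250, target_sites = 5000,
                               seed = 54)
  pcs <- sample_pcs(pair$gwas, 2)
  ind <- as.numeric(pair$gwas$labels == "B")
  expect_gt(cor(pcs[[1]]$values, ind)^2, 0.9)
  expect_gt(pcs[[1]]$eigenvalue, 1 + sqrt(500 / 5000))
})

test_that("PC accuracy theory evaluates the phase-transition formula", {
  expect_equal(pc_accuracy_theory(1 + sqrt(0.5), M = 500, L = 1000), 0)
  expect_equal(pc_accuracy_theory(1e9, M = 1000, L = 1000), 1,
               tolerance = 1e-6)
  expect_equal(pc_accuracy_theory(4, M = 1000, L = 1000),
               (1 - 1 / 9) / (1 + 1 / 3), tolerance = 1e-12)
  expect_equal(pc_accuracy_theory(1.0, M = 100, L = 10000), 0)
})

test_that("axis error is a sign-invariant squared-correlation complement", {
  set.seed(55)
  a <- new_structure_axis(rnorm(50))
  expect_equal(axis_error(a, a)$error, 0, tolerance = 1e-12)
  neg <- new_structure_axis(-a$raw)
  expect_equal(axis_error(neg, a)$error, 0, tolerance = 1e-12)
  b <- rnorm(50)
  b_perp <- residuals(lm(b ~ a$values))
  expect_equal(axis_error(new_structure_axis(b_perp), a)$error, 1,
               tolerance = 1e-12)
  expect_error(axis_error(a, new_structure_axis(rnorm(10))), "length")
})

test_that("grid error decomposition reproduces a hand-computed example and recovers planted noise", {
  ## 2 demes x 2 individuals x 2 replicates, worked by hand
  x <- cbind(c(1, 3, 10, 14), c(3, 5, 12, 12))
  labs <- c("d1", "d1", "d2", "d2")
  ## replicate within-deme sample variances: (2,8) and (2,0) -> mean 3
  ## deme means per replicate: d1 (2,4), d2 (12,12) -> across-rep vars (2,0) -> mean 1
  ## total variances: var(c(1,3,10,14)) = 34.9167, var(c(3,5,12,12)) = 21.5833
  within <- mean(c(mean(c(2, 8)), mean(c(2, 0))))
  across <- mean(c(var(c(2, 4)), var(c(12, 12))))
  total <- mean(c(var(x[, 1]), var(x[, 2])))
  est <- grid_error_direct(x, labs)
  expect_equal(est$error, (within + across) / total, tolerance = 1e-12)
  expect_equal(unname(est$components["within_deme"] + est$components["deme_mean"]),
               est$error, tolerance = 1e-12)
  expect_false(est$bound)
  ## single replicate: lower bound only
  est1 <- grid_error_direct(x[, 1, drop = FALSE], labs)
  expect_true(est1$bound)
  expect_true(is.na(est1$components["deme_mean"]))
  ## deme-constant values identical across replicates -> error 0
  const <- cbind(rep(c(1, 5), each = 2), rep(c(1, 5), each = 2))
  expect_equal(grid_error_direct(const, labs)$error, 0)
  ## planted signal + noise: recovers the noise fraction within 0.03 at H = 50
  set.seed(56)
  J <- 36; m <- 20; H <- 50
  truth <- rnorm(J, sd = sqrt(0.9))
  reps <- vapply(seq_len(H), function(h) {
    rep(truth, each = m) + rnorm(J * m, sd = sqrt(0.1))
  }, numeric(J * m))
  est2 <- grid_error_direct(reps, rep(sprintf("d%02d", 1:J), each = m))
  ## target uses the realized between-deme signal variance of this draw
  planted <- 0.1 / (var(rep(truth, each = m)) + 0.1)
  expect_lt(abs(est2$error - planted), 0.03)
  ## iid noise with no deme signal -> error near 1
  noise <- matrix(rnorm(J * m * H), J * m, H)
  expect_gt(grid_error_direct(noise, rep(sprintf("d%02d", 1:J), each = m))$error,
            0.95)
})

test_that("the PC error bound uses only within-deme variance on the standardized scale", {
  ## demes (0,0 | 1,3): standardized to variance 1 then within-deme variance
  x <- c(0, 0, 1, 3)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expected <- mean(c(var(z[1:2]), var(z[3:4])))
  est <- grid_error_pc_bound(cbind(x), c("d1", "d1", "d2", "d2"))
  expect_equal(est$error, expected, tolerance = 1e-12)
  expect_true(est$bound)
  ## deme-constant PCs in every replicate -> bound 0
  const <- cbind(rep(c(1, 5), each = 2), rep(c(-1, 2), each = 2))
  expect_equal(grid_error_pc_bound(const, c("d1", "d1", "d2", "d2"))$error, 0)
  ## iid noise -> bound near 1
  set.seed(57)
  noise <- matrix(rnorm(36 * 10 * 20), 360, 20)
  expect_gt(grid_error_pc_bound(noise, rep(sprintf("d%02d", 1:36), each = 10))$error,
            0.9)
})

test_that("PC decomposition of an axis behaves like an orthogonal projection", {
  set.seed(58)
  M <- 40
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(M * (M - 1)), M))))[, -1]  # mean-zero basis
  pcs <- Q[, 1:10]
  ## axis equal to the first PC: all weight on component 1
  d1 <- pc_decomposition_of_axis(Q[, 1], pcs)
  expect_equal(d1$cum_r2[1], 1, tolerance = 1e-10)
  expect_equal(d1$eta[-1], rep(0, 9), tolerance = 1e-10)
  ## axis orthogonal to the span: nothing explained
  d2 <- pc_decomposition_of_axis(Q[, 11], pcs)
  expect_equal(max(abs(d2$eta)), 0, tolerance = 1e-10)
  expect_equal(d2$cum_r2[10], 0, tolerance = 1e-10)
  ## full mean-zero basis explains any axis completely
  axis <- rnorm(M)
  d3 <- pc_decomposition_of_axis(axis, Q)
  expect_equal(d3$cum_r2[M - 1], 1, tolerance = 1e-8)
  expect_true(all(diff(d3$cum_r2) >= -1e-12))
  expect_error(pc_decomposition_of_axis(axis, matrix(rnorm(M * 3), M)),
               "orthonormal")
})
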