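test_that("the tree bias experiment is deterministic and correctly shaped", {
  cfg <- tree_bias_config("smoke", n_per_pop = 40, target_sites = 300,
                          n_score = 30, deltas = c(0, 0.1), n_replicates = 3,
                          corrections = c("none", "fgr_true", "fgr_hat"),
                          seed = 111)
  res <- run_tree_bias_experiment(cfg)
  expect_equal(nrow(res), 2 * 2 * 3)  # topologies x deltas x corrections
  expect_named(res, c("topology", "delta", "correction", "mean_bias", "ci95",
                      "H", "f4_mean", "predicted"))
  expect_true(all(res$H == 3))
  res2 <- run_tree_bias_experiment(cfg)
  expect_identical(res, res2)
  ## the unconfounded topology has a degenerate true axis, so the fgr_true
  ## rows coincide with the uncorrected rows there
  un <- subset(res, topology == "unconfounded")
  expect_equal(subset(un, correction == "fgr_true")$mean_bias,
               subset(un, correction == "none")$mean_bias)
  expect_error(tree_bias_config("smoke", bogus = 1), "unknown config field")
})

test_that("estimator errors fall with L and track panel overlap (toy-model sweep)", {
  cfg <- estimator_error_config("smoke", n_per_pop = 250,
                                L_values = c(1000, 8000), n_replicates = 4,
                                shallow_splits = c(0, 10), seed = 112)
  res <- run_estimator_error_experiment(cfg)
  expect_equal(nrow(res), 4)
  for (ts in c(0, 10)) {
    sub <- res[res$shallow_split == ts, ]
    ## error decreases as the number of SNPs grows, for both estimators
    expect_lt(sub$error_fgr[2], sub$error_fgr[1])
    expect_lt(sub$error_pc1[2], sub$error_pc1[1])
  }
  ## complete overlap, M/L appreciable: the direct estimator beats PC1
  co <- res[res$shallow_split == 0, ]
  expect_lt(co$error_fgr[co$L == 1000], co$error_pc1[co$L == 1000])
  ## minimal overlap (splits 12/10): PCA outperforms the direct estimator
  mo <- res[res$shallow_split == 10, ]
  expect_lt(mo$error_pc1[mo$L == 8000], mo$error_fgr[mo$L == 8000])
})

test_that("grid smoke run: latitudinal confounding is corrected by both estimators", {
  cfg <- grid_experiment_config("smoke", samples_per_deme = 40,
                                target_sites = 6000, n_score = 300,
                                L_sweep = c(1500, 6000), delta = 0.2,
                                scenarios = "latitude",
                                corrections = c("none", "fgr_hat", "pcs10"),
                                n_replicates = 10, seed = 11)
  res <- run_grid_experiment(cfg)
  b <- res$bias
  lat <- function(corr) b[b$correction == corr, ]
  ## uncorrected scores recapitulate the confounder: biased test, and the
  ## per-deme score map climbs with latitude
  expect_gt(lat("none")$mean_bias, lat("none")$ci95)
  m <- res$maps[res$maps$correction == "none", ]
  expect_gt(cor(m$mean_score, m$row), 0.5)
  ## either correction protects the latitude test (99% coverage per cell)
  for (corr in c("fgr_hat", "pcs10")) {
    expect_lt(abs(lat(corr)$mean_bias), 1.5 * lat(corr)$ci95)
  }
  ## exchangeability-based error estimates fall with L
  ef <- res$errors[res$errors$estimator == "fgr_hat", ]
  expect_lt(ef$error[ef$L == 6000], ef$error[ef$L == 1500])
  e1 <- res$errors[res$errors$estimator == "pc1", ]
  expect_lt(e1$error[e1$L == 6000], e1$error[e1$L == 1500])
})

test_that("grid smoke run: the direct estimator protects the single-deme test, ten PCs do not", {
  cfg <- grid_experiment_config("smoke", samples_per_deme = 40,
                                target_sites = 8000, n_score = 300,
                                L_sweep = c(2000, 8000), delta = 0.6,
                                scenarios = "single_deme",
                                corrections = c("none", "fgr_hat", "pcs10"),
                                n_replicates = 20, seed = 11)
  res <- run_grid_experiment(cfg)
  b <- res$bias
  g <- function(corr) b[b$correction == corr, ]
  expect_gt(g("none")$mean_bias, g("none")$ci95)        # uncorrected: biased
  expect_lt(abs(g("fgr_hat")$mean_bias), g("fgr_hat")$ci95)  # FGr: protected
  expect_gt(g("pcs10")$mean_bias, g("pcs10")$ci95)      # 10 PCs: still biased
  expect_gt(abs(g("pcs10")$mean_bias), abs(g("fgr_hat")$mean_bias))
  ## the error of the direct estimator falls as L grows
  ef <- res$errors[res$errors$estimator == "fgr_hat", ]
  expect_lt(ef$error[ef$L == 8000], ef$error[ef$L == 2000])
})

test_that("a planted signal survives the direct-estimator correction", {
  cfg <- signal_experiment_config("smoke", n_per_pop = 250,
                                  target_sites = 2000, n_score = 100,
                                  thetas = c(0.5, 0.62), deltas = c(0, 0.1),
                                  n_replicates = 10, seed = 113)
  res <- run_signal_experiment(cfg)
  pick <- function(th, de, corr) {
    res[res$theta == th & res$delta == de & res$correction == corr, ]
  }
  ## no signal, no confounding: q_hat consistent with zero
  expect_lt(abs(pick(0.5, 0, "none")$mean_q_hat),
            1.5 * pick(0.5, 0, "none")$ci95)
  expect_lt(abs(pick(0.5, 0, "fgr_hat")$mean_q_hat),
            1.5 * pick(0.5, 0, "fgr_hat")$ci95)
  ## theta > 0.5: a real association survives the correction
  expect_gt(pick(0.62, 0, "fgr_hat")$mean_q_hat,
            pick(0.62, 0, "fgr_hat")$ci95)
  ## the corrected estimate is not attenuated by more than 20% relative to
  ## the true q
  expect_gt(pick(0.62, 0, "fgr_hat")$mean_q_hat,
            0.8 * pick(0.62, 0, "fgr_hat")$mean_q_true)
  ## pure confounding (theta = 0.5, delta > 0): the uncorrected statistic is
  ## pushed upward and the correction shrinks the excess over the truth
  un_excess <- pick(0.5, 0.1, "none")$mean_q_hat -
    pick(0.5, 0.1, "none")$mean_q_true
  co_excess <- pick(0.5, 0.1, "fgr_hat")$mean_q_hat -
    pick(0.5, 0.1, "fgr_hat")$mean_q_true
  expect_gt(un_excess, 0)
  expect_lt(abs(co_excess), abs(un_excess))
})
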