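# Graded-threshold two-group simulator.

test_that("generation is deterministic for a fixed seed and groups differ only via the config", {
  cfg <- sim_config(n_per_group = c(50, 60), n_items = 10, seed = 11)
  m1 <- generate_responses(cfg)
  m2 <- generate_responses(cfg)
  expect_identical(m1$values, m2$values)
  expect_identical(as.character(m1$group),
                   rep(c("case", "comparison"), c(50, 60)))
  expect_false(anyNA(m1$values))
  expect_true(all(m1$values >= 1 & m1$values <= 7))
})

test_that("zero group shift yields a near-zero discrimination profile", {
  cfg <- sim_config(n_per_group = c(1000, 1000), n_items = 10,
                    reverse_items = character(), seed = 4)
  d <- item_discrimination(generate_responses(cfg))
  expect_lt(mean(abs(d)), 0.1)
})

test_that("observed d matches the threshold-model oracle under a calibrated shift", {
  cfg <- sim_config(n_per_group = c(2000, 2000), n_items = 4, n_factors = 1,
                    loadings = matrix(0.7, 4, 1), factor_correlation = 1,
                    reverse_items = character(), seed = 8)
  cfg <- induce_d_profile(1.5, cfg)
  d_pred <- vapply(seq_len(4), function(j)
    implied_observed_d(cfg$thresholds[j, ], cfg$group_shift[j]), numeric(1))
  expect_equal(d_pred, rep(1.5, 4), tolerance = 1e-3)
  d_obs <- item_discrimination(generate_responses(cfg))
  expect_true(all(abs(d_obs - d_pred) < 0.15))
})

test_that("factor scores of generated data reproduce the configured factor correlation", {
  L <- matrix(0, 10, 2)
  L[1:5, 1] <- 0.7
  L[6:10, 2] <- 0.7
  cfg <- sim_config(n_per_group = c(500, 500), n_items = 10, n_factors = 2,
                    loadings = L, factor_correlation = 0.6, group_shift = 0,
                    reverse_items = character(), seed = 12)
  m <- generate_responses(cfg)
  e <- efa_paf(m$values, n_factors = 2)
  fs <- factor_scores(m$values, e$loadings, e$phi)
  expect_lt(abs(abs(stats::cor(fs$scores)[1, 2]) - 0.6), 0.1)
})

test_that("d-profile calibration round-trips the emulated discrimination range", {
  cfg <- sim_config(n_per_group = c(20000, 20000), n_items = 2, n_factors = 1,
                    loadings = matrix(0.7, 2, 1), factor_correlation = 1,
                    reverse_items = character(), seed = 31)
  cfg <- induce_d_profile(c(0.80, 2.44), cfg)
  d <- item_discrimination(generate_responses(cfg))
  expect_gt(d[1], 0.7); expect_lt(d[1], 0.9)
  expect_gt(d[2], 2.3); expect_lt(d[2], 2.6)
})

test_that("zero target d yields zero shift and unreachable targets name the item", {
  cfg <- sim_config(n_items = 3, seed = 1)
  expect_identical(induce_d_profile(0, cfg)$group_shift, rep(0, 3))
  cfg2 <- sim_config(n_items = 2, n_factors = 1,
                     loadings = matrix(0.7, 2, 1), factor_correlation = 1,
                     thresholds = c(-2.5, -2, -1.5, -1, -0.5, 0), seed = 1)
  expect_error(induce_d_profile(50, cfg2), "IP1")
})

test_that("reverse-keyed items are emitted on the reversed scale", {
  cfg <- sim_config(n_per_group = c(2000, 2000), n_items = 6, n_factors = 1,
                    loadings = matrix(0.7, 6, 1), factor_correlation = 1,
                    group_shift = 1, reverse_items = "IP6", seed = 3)
  m <- generate_responses(cfg)
  raw_d <- vapply(1:6, function(j)
    cohens_d(m$values[m$group == "case", j],
             m$values[m$group == "comparison", j]), numeric(1))
  expect_true(all(raw_d[1:5] > 0))
  expect_lt(raw_d[6], 0)            # high trait -> low raw rating
  keyed_d <- item_discrimination(m, reverse = "IP6")
  expect_gt(keyed_d["IP6"], 0)
})

test_that("marginal category frequencies match the threshold-model probabilities", {
  cfg <- sim_config(n_per_group = c(6000, 6000), n_items = 3, n_factors = 1,
                    loadings = matrix(0.6, 3, 1), factor_correlation = 1,
                    reverse_items = character(), seed = 17)
  m <- generate_responses(cfg)
  comp <- m$values[m$group == "comparison", , drop = FALSE]
  for (j in 1:3) {
    probs <- scalenet:::category_probs(cfg$thresholds[j, ])
    obs <- tabulate(comp[, j], 7)
    keep <- probs > 0
    gof <- stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("zero noninvariance perturbation reproduces the invariant output exactly", {
  base <- sim_config(n_per_group = c(100, 100), n_items = 8, seed = 5)
  pert <- sim_config(n_per_group = c(100, 100), n_items = 8, seed = 5,
                     noninvariance = list(
                       loadings = matrix(0, 8, 2),
                       thresholds = matrix(0, 8, 6)))
  expect_identical(generate_responses(base)$values,
                   generate_responses(pert)$values)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_items = 3, thresholds = c(0, -1, 1, 2, 3, 4)),
               "strictly increasing")
  expect_error(sim_config(n_items = 3, n_factors = 1,
                          loadings = matrix(1.2, 3, 1),
                          factor_correlation = 1),
               "communality")
  expect_error(sim_config(n_factors = 2,
                          factor_correlation = matrix(c(1, 1.2, 1.2, 1), 2)),
               "positive definite")
})
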