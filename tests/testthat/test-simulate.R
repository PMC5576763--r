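test_that("simulate_triple is seeded, flagged and moment-correct", {
  cfg <- me_config(n = 300, seed = 12)
  tr <- simulate_triple(cfg)
  expect_identical(tr, simulate_triple(cfg))
  expect_false(tr$degenerate)
  expect_true(all(tr$E %in% 0:1))
  # maf -> 0 limit: constant genotype is flagged
  tr0 <- simulate_triple(me_config(n = 20, maf = 1e-9, seed = 1))
  expect_true(tr0$degenerate)
  # vanishing measurement noise: A converges to A_true
  trc <- simulate_triple(me_config(n = 2000, sigmaA2_sq = 1e-8, seed = 2))
  expect_gt(stats::cor(trc$A, trc$A_true), 0.999)
})

test_that("simulate_triple variance decomposition matches the model", {
  cfg <- me_config(n = 1e5, maf = 0.1, sigmaA1_sq = 1, sigmaA2_sq = 0.5,
                   sigmaB_sq = 2, seed = 7)
  tr <- simulate_triple(cfg)
  # var(A) = var(A_true) + sigmaA2^2, var(B) = 1 + sigmaB^2 (unit-variance
  # standardized A_true feeds B)
  expect_equal(stats::var(tr$A), stats::var(tr$A_true) + 0.5,
               tolerance = 0.02)
  expect_equal(stats::var(tr$B), 3, tolerance = 0.05)
  # headline setting: one third of B's variance comes from A_true
  expect_equal(stats::cor(tr$B, znormalize(tr$A_true))^2, 1 / 3,
               tolerance = 0.02)
})

test_that("grid_scan covers the stated bounds and masks weak eQTLs", {
  sc <- grid_scan(me_config(n = 150, seed = 5), grid_points = 5)
  sig <- sort(unique(sc$sigmaA1_sq))
  expect_equal(range(sig), c(1e-2, 1e2))
  expect_identical(nrow(sc), 5L * 5L * 5L)  # tiles x tests 1..5
  expect_setequal(unique(sc$test_id), 1:5)
  # masked tiles are exactly those with a non-significant primary test
  t1 <- sc[sc$test_id == 1L, ]
  expect_identical(t1$masked, !is.finite(t1$p_value) | t1$p_value > 1e-6)
  # strong-eQTL corner must survive masking
  expect_false(t1$masked[t1$sigmaA1_sq == 1e-2 & t1$sigmaA2_sq == 1e-2])
})

test_that("network generator honours density and confounding switches", {
  cfg0 <- network_config(n_genes = 50, n_samples = 30, edge_density = 0,
                         seed = 2)
  ds0 <- generate_network_dataset(cfg0)
  expect_identical(nrow(ds0$edges), 0L)
  expect_false(any(ds0$confounded))
  # no explicit confounders => no shared direct upstream regulators
  ds1 <- generate_network_dataset(
    network_config(n_genes = 200, n_samples = 30,
                   confounder_fraction = 0, seed = 3))
  expect_gt(nrow(ds1$edges), 0L)
  expect_false(any(ds1$confounded))
  ds2 <- generate_network_dataset(
    network_config(n_genes = 200, n_samples = 30,
                   confounder_fraction = 1, seed = 3))
  expect_gt(sum(ds2$confounded), 0)
  # seeded determinism
  expect_identical(ds2$expression,
                   generate_network_dataset(ds2$config)$expression)
})

test_that("generated networks are acyclic with consistent labels", {
  ds <- generate_network_dataset(
    network_config(n_genes = 100, n_samples = 30, seed = 9))
  idx_from <- match(ds$edges$from, rownames(ds$expression))
  idx_to <- match(ds$edges$to, rownames(ds$expression))
  expect_true(all(idx_from < idx_to))  # topological order = gene order
  expect_false(any(diag(ds$confounded)))
  # confounded labels are symmetric as ordered-pair flags
  expect_identical(ds$confounded, t(ds$confounded))
})
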