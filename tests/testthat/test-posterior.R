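test_that("estimate_pi0 recovers the null proportion", {
  spec <- null_spec(2, 300, 3)
  set.seed(21)
  # pure null
  expect_gte(estimate_pi0(d_sample(spec, 5000), spec), 0.9)
  expect_lte(estimate_pi0(d_sample(spec, 5000), spec), 1.0)
  # 30% null + far-shifted alternatives
  v <- c(d_sample(spec, 3000), d_sample(spec, 7000) + 0.15)
  expect_lt(abs(estimate_pi0(v, spec) - 0.3), 0.05)
  expect_error(estimate_pi0(rep(0.1, 200), spec), "degenerate")
})

test_that("all-null samples yield near-zero posteriors (alt direction)", {
  spec <- null_spec(0, 300)
  set.seed(8)
  m <- build_posterior_map(d_sample(spec, 1e4), spec)
  expect_true(all(m$posterior <= 0.1))
  expect_identical(m$direction, "increasing")
  expect_true(all(diff(m$posterior) >= 0))
})

test_that("test-3 maps are decreasing in LLR", {
  spec3 <- null_spec(3, 300, 3)
  set.seed(9)
  v <- c(d_sample(spec3, 5000), d_sample(spec3, 5000) + 0.1)
  m <- build_posterior_map(v, spec3)
  expect_identical(m$direction, "decreasing")
  expect_true(all(diff(m$posterior) <= 0))
  expect_true(all(m$posterior >= 0 & m$posterior <= 1))
  # high-LLR values (clear alternative of the surrounding tests) get a
  # low chain-model posterior, low-LLR values a high one
  expect_gt(posterior_lookup(m, 0.001), posterior_lookup(m, 0.3))
})

test_that("posterior maps are calibrated on genuine-effect mixtures", {
  set.seed(33)
  mix <- make_llr_mixture(1e4, pi0 = 0.7)
  m <- build_posterior_map(mix$z, mix$spec)
  post <- posterior_lookup(m, mix$z)
  # mean posterior tracks the true alternative fraction
  expect_lt(abs(mean(post) - 0.3), 0.05)
  # local calibration: observed alt fraction per posterior decile
  bins <- cut(post, seq(0, 1, 0.1), include.lowest = TRUE)
  obs <- tapply(mix$truth, bins, mean)
  pred <- tapply(post, bins, mean)
  cnt <- as.integer(table(bins))
  ok <- cnt >= 100
  expect_true(all(abs(obs[ok] - pred[ok]) <= 0.1))
})

test_that("bins with real mass but no null mass get posterior near 1", {
  spec <- null_spec(0, 300)
  set.seed(2)
  v <- c(d_sample(spec, 2000), 0.5 + 0.01 * stats::runif(200))
  m <- build_posterior_map(v, spec)
  expect_gte(posterior_lookup(m, 0.505), 0.95)
  # out-of-range values map to the nearest edge
  expect_identical(posterior_lookup(m, 99), m$posterior[length(m$posterior)])
  expect_identical(posterior_lookup(m, -1), m$posterior[1L])
  expect_true(is.na(posterior_lookup(m, NA_real_)))
})

test_that("posteriors(): per-pair rows rank strong alternatives highly", {
  set.seed(44)
  mix <- make_llr_mixture(1e4, pi0 = 0.5, beta_range = c(0.5, 1))
  p <- posteriors(matrix(mix$z, nrow = 1), mix$spec, mode = "per-pair")
  expect_gt(auroc(as.numeric(p), mix$truth), 0.9)
})

test_that("per-pair and pooled agree when rows share one mixture", {
  set.seed(55)
  spec <- null_spec(2, 300, 3)
  z <- matrix(c(d_sample(spec, 4000), d_sample(spec, 4000) + 0.12), 4,
              byrow = FALSE)[, sample(2000)]
  pp <- posteriors(z, spec, mode = "per-pair")
  pl <- posteriors(z, spec, mode = "pooled")
  expect_lt(mean(abs(pp - pl)), 0.1)
})

test_that("short rows fall back to the pooled map with a warning", {
  set.seed(66)
  spec <- null_spec(0, 300)
  z <- matrix(d_sample(spec, 200), 4, 50)  # 50 < min_targets
  msgs <- capture.output(
    pp <- posteriors(z, spec, mode = "per-pair"), type = "message")
  expect_true(any(grepl("falling back to pooled", msgs)))
  expect_identical(pp, posteriors(z, spec, mode = "pooled"))
})
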