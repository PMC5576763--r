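test_that("auroc matches the exhaustive pairwise oracle", {
  expect_equal(auroc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  set.seed(15)
  for (rep in 1:5) {
    s <- sample(stats::rnorm(12), 20, replace = TRUE)  # forces ties
    y <- stats::rbinom(20, 1, 0.4)
    if (sum(y) %in% c(0, 20)) next
    expect_equal(auroc(s, y), auroc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("aupr matches the quadrature interpolation oracle", {
  expect_equal(aupr(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  # constant scores: precision = prevalence everywhere
  expect_equal(aupr(rep(1, 10), c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0)), 0.2)
  set.seed(16)
  for (rep in 1:5) {
    s <- sample(stats::rnorm(8), 10, replace = TRUE)
    y <- c(1, 1, 1, stats::rbinom(7, 1, 0.3))[sample.int(10)]
    expect_equal(aupr(s, y), aupr_oracle(s, y), tolerance = 1e-7)
  }
  expect_error(aupr(1:4, c(0, 0, 0, 0)), "no positives")
})

test_that("metrics are invariant to monotone maps and tie shuffles", {
  set.seed(17)
  s <- round(stats::rnorm(40), 1)
  y <- stats::rbinom(40, 1, 0.3)
  expect_equal(auroc(s, y), auroc(exp(2 * s), y), tolerance = 1e-12)
  expect_equal(aupr(s, y), aupr(stats::pnorm(s), y), tolerance = 1e-12)
  perm <- order(s, stats::runif(40))  # reorder within tie groups
  expect_equal(auroc(s[perm], y[perm]), auroc(s, y), tolerance = 1e-12)
  expect_equal(aupr(s[perm], y[perm]), aupr(s, y), tolerance = 1e-12)
})

test_that("aupr beats prevalence for informative rankings", {
  set.seed(18)
  y <- stats::rbinom(200, 1, 0.1)
  s <- y + stats::rnorm(200, sd = 0.8)
  expect_gt(aupr(s, y), mean(y))
})

test_that("local precision bins partition and split by confounding", {
  set.seed(19)
  m <- 5000L
  s <- stats::runif(m)
  conf <- stats::rbinom(m, 1, 0.3) == 1
  lp_all_true <- local_precision_by_confounding(s, rep(TRUE, m), conf)
  expect_true(all(lp_all_true$precision[lp_all_true$n_pairs > 0] == 1))
  expect_identical(sum(lp_all_true$n_pairs), m)
  expect_identical(length(default_rank_bins()), 10L)  # nine ranges
  y <- s > 0.9
  lp <- local_precision_by_confounding(s, y, conf)
  expect_identical(nrow(lp), 18L)
  # empty subgroup: NA precision, zero count
  expect_true(all(is.na(lp$precision[lp$n_pairs == 0])))
  # top bins of a well-ranked score are purer than bottom bins
  expect_gt(stats::weighted.mean(lp$precision[lp$bin_hi <= 1],
                                 lp$n_pairs[lp$bin_hi <= 1], na.rm = TRUE),
            stats::weighted.mean(lp$precision[lp$bin_lo >= 10],
                                 lp$n_pairs[lp$bin_lo >= 10], na.rm = TRUE))
})

test_that("precision_vs_estimated reports cutoff precision and counts", {
  s <- c(0.95, 0.9, 0.55, 0.5, 0.2)
  y <- c(1, 1, 1, 0, 0)
  pv <- precision_vs_estimated(s, y)
  expect_identical(pv$threshold, seq(0.1, 0.9, by = 0.1))
  expect_identical(pv$n_predictions[pv$threshold == 0.9], 2L)
  expect_equal(pv$precision[pv$threshold == 0.5], 0.75)
  over <- precision_vs_estimated(s, y, thresholds = 1 + 1e-9)
  expect_identical(over$n_predictions, 0L)
  expect_true(is.na(over$precision))
})

test_that("subsample_evaluate has zero spread at N = n", {
  ds <- generate_network_dataset(
    network_config(n_genes = 40, n_samples = 60, seed = 6))
  res <- subsample_evaluate(ds$expression, ds$genotypes, ds$pairs,
                            ds$edges, N = 60, k = 2, seed = 1,
                            config = run_config(mode = "pooled"),
                            which = "P")
  expect_equal(res$sd, rep(0, nrow(res)), tolerance = 1e-12)
  expect_equal(unique(res$k), 2)
  res2 <- subsample_evaluate(ds$expression, ds$genotypes, ds$pairs,
                             ds$edges, N = 40, k = 3, seed = 1,
                             config = run_config(mode = "pooled"),
                             which = "P")
  expect_true(all(res2$se <= res2$sd + 1e-15))
  expect_true(all(res2$mean >= 0 & res2$mean <= 1))
})

test_that("prediction_curves produce valid ROC/PR coordinates", {
  set.seed(20)
  y <- stats::rbinom(100, 1, 0.3)
  s <- y + stats::rnorm(100)
  cv <- prediction_curves(s, y)
  expect_equal(cv$roc$fpr[1], 0)
  expect_equal(utils::tail(cv$roc$tpr, 1), 1)
  expect_true(all(diff(cv$pr$recall) >= 0))
})
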