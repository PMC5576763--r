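test_that("llr_correlation handles exact independence and identity", {
  n <- 20
  A <- supernormalize(seq_len(n))
  # Gram-Schmidt: B orthogonal to both the constant and A, standardized
  x <- stats::rnorm(n)
  b <- x - mean(x) - sum(x * A) / sum(A^2) * A
  B <- b / sqrt(mean(b^2))
  expect_equal(llr_correlation(A, B), 0, tolerance = 1e-9)
  # rho = 1 up to floating point: large but finite
  big <- llr_correlation(A, A)
  expect_true(is.finite(big) && big > 100)
  expect_error(llr_correlation(A, B[-1]), "equal length")
  expect_error(llr_correlation(seq_len(n), B), "not supernormalized")
})

test_that("llr_primary handles flat and saturated group means", {
  E <- encode_genotypes(rep(c(0, 1), each = 4))
  # per-group zero means: sigma_A^2 = 1, LLR = 0
  A0 <- supernormalize(c(-2, -1, 1, 2, -2, -1, 1, 2))
  expect_equal(llr_primary(E, A0), 0, tolerance = 1e-9)
  # A equal to its genotype-group means: zero residual, clamp-limited
  A1 <- znormalize(E$values)
  expect_true(is.finite(llr_primary(E, A1)) && llr_primary(E, A1) > 100)
  expect_error(llr_primary(encode_genotypes(rep(1, 8)), A0),
               "degenerate genotype")
})

test_that("llr identities I1 and I2 hold over random triples", {
  set.seed(101)
  for (rep in 1:50) {
    tr <- rand_triple(30, beta_b = stats::runif(1, -1, 1),
                      pleio = stats::runif(1, 0, 0.8))
    p <- llr_profile(tr$E, tr$A, tr$B)
    expect_lt(abs(p$llr4 - (p$llr2 + p$llr5)), 1e-9)
    expect_lt(abs(p$llr3 - (p$llr4 - p$llr0)), 1e-9)
    for (t in 0:5) expect_gte(p[[paste0("llr", t)]], -1e-9)
  }
})

test_that("all LLRs are invariant to joint sample permutations", {
  set.seed(5)
  tr <- rand_triple(40)
  p1 <- unlist(llr_profile(tr$E, tr$A, tr$B)[paste0("llr", 0:5)])
  perm <- sample.int(40)
  E2 <- encode_genotypes(tr$E$values[perm])
  p2 <- unlist(llr_profile(E2, tr$A[perm], tr$B[perm])[paste0("llr", 0:5)])
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("batched profiles equal elementwise scalar calls", {
  set.seed(9)
  n <- 35
  tr <- rand_triple(n)
  Bm <- std_rows(matrix(stats::rnorm(100 * n), 100) +
                   outer(stats::runif(100, -0.5, 0.5), tr$A))
  bt <- llr_profile_batch(tr$E, tr$A, Bm)
  sc <- t(vapply(seq_len(100), function(i)
    unlist(llr_profile(tr$E, tr$A, Bm[i, ])[paste0("llr", 0:5)]),
    numeric(6)))
  expect_lt(max(abs(bt - unname(sc))), 1e-12)
})

test_that("profile of (E, A, A) saturates test 0 and matches tests 1/2", {
  set.seed(13)
  tr <- rand_triple(30)
  p <- llr_profile(tr$E, tr$A, tr$A)
  expect_true(is.finite(p$llr0) && p$llr0 > 100)
  expect_equal(p$llr2, p$llr1, tolerance = 1e-9)
})

test_that("closed forms match the numeric ML oracle", {
  set.seed(77)
  for (t in 0:5) {
    for (rep in 1:2) {
      tr <- rand_triple(sample(20:60, 1), beta_b = stats::runif(1, 0, 0.8),
                        pleio = stats::runif(1, 0, 0.5))
      expect_equal(closed_llr(t, tr$E, tr$A, tr$B),
                   oracle_llr(t, tr$E, tr$A, tr$B), tolerance = 1e-6)
    }
  }
})

test_that("trivariate tests reject degenerate genotypes and raw data", {
  A <- supernormalize(stats::rnorm(10))
  B <- supernormalize(stats::rnorm(10))
  expect_error(llr_independence(rep(0, 10), A, B), "degenerate genotype")
  expect_error(llr_relevance(rep(0:1, 5), stats::rnorm(10), B),
               "not supernormalized")
})
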