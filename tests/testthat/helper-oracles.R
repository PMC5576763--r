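# Shared helpers: row standardization, random anchored triples, numeric
# maximum-likelihood oracles for the six tests, an exhaustive AUROC
# oracle, a quadrature AUPR oracle, and posterior-mixture builders.

std_rows <- function(M) {
  M <- M - rowMeans(M)
  M / sqrt(rowMeans(M^2))
}

# Random (E, A, B) with real E -> A signal and tunable A -> B / pleiotropy.
rand_triple <- function(n, n_cat = 3L, beta_a = 1, beta_b = 0.4,
                        pleio = 0) {
  repeat {
    E <- encode_genotypes(sample.int(n_cat, n, replace = TRUE) - 1L)
    if (E$n_v >= 2L) break
  }
  A <- supernormalize(stats::rnorm(n) + beta_a * E$values)
  B <- supernormalize(beta_b * A + pleio * E$values + stats::rnorm(n))
  list(E = E, A = A, B = B)
}

# Two-stage numeric maximization (Nelder-Mead then BFGS polish).
ll_maximize <- function(f, p0) {
  o1 <- stats::optim(p0, f, control = list(fnscale = -1, maxit = 2e4,
                                           reltol = 1e-15))
  o2 <- stats::optim(o1$par, f, method = "BFGS",
                     control = list(fnscale = -1, maxit = 1e4,
                                    reltol = 1e-15))
  max(o1$value, o2$value)
}

# Numeric ML oracle: maximizes each hypothesis' log-likelihood over its
# free parameters and returns the LLR. Independent of the closed forms.
oracle_llr <- function(test_id, E, A, B = NULL) {
  n <- E$n
  idx <- match(E$values, as.integer(names(E$n_j)))
  k <- E$n_v
  ll_cat <- function(x, mu, ls) sum(stats::dnorm(x, mu[idx], exp(ls),
                                                 log = TRUE))
  mu0A <- as.numeric(tapply(A, idx, mean))
  if (test_id == 0L) {
    alt <- function(p) {
      sA <- exp(p[1]); sB <- exp(p[2]); r <- tanh(p[3])
      -n * log(2 * pi * sA * sB * sqrt(1 - r^2)) -
        sum(A^2 / sA^2 - 2 * r * A * B / (sA * sB) + B^2 / sB^2) /
        (2 * (1 - r^2))
    }
    nul <- function(p) sum(stats::dnorm(A, 0, exp(p[1]), log = TRUE)) +
      sum(stats::dnorm(B, 0, exp(p[2]), log = TRUE))
    return(ll_maximize(alt, c(0.1, 0.1, 0.2)) -
             ll_maximize(nul, c(0.1, 0.1)))
  }
  if (test_id %in% c(1L, 2L)) {
    x <- if (test_id == 1L) A else B
    mu0 <- as.numeric(tapply(x, idx, mean))
    alt <- function(p) ll_cat(x, p[1:k], p[k + 1])
    nul <- function(p) sum(stats::dnorm(x, p[1], exp(p[2]), log = TRUE))
    return(ll_maximize(alt, c(mu0 + 0.05, 0.1)) -
             ll_maximize(nul, c(0.05, 0.1)))
  }
  nu0 <- as.numeric(tapply(B, idx, mean))
  if (test_id == 3L) {
    alt <- function(p) {
      mu <- p[1:k]; nu <- p[(k + 1):(2 * k)]
      sA <- exp(p[2 * k + 1]); sB <- exp(p[2 * k + 2])
      r <- tanh(p[2 * k + 3])
      a <- A - mu[idx]; b <- B - nu[idx]
      -n * log(2 * pi * sA * sB * sqrt(1 - r^2)) -
        sum(a^2 / sA^2 - 2 * r * a * b / (sA * sB) + b^2 / sB^2) /
        (2 * (1 - r^2))
    }
    nul <- function(p) ll_cat(A, p[1:k], p[k + 1]) +
      sum(stats::dnorm(B, p[k + 3] * A, exp(p[k + 2]), log = TRUE))
    return(ll_maximize(alt, c(mu0A + 0.05, nu0 - 0.05, 0.1, 0.1, 0.1)) -
             ll_maximize(nul, c(mu0A + 0.05, 0.1, 0.1, 0.2)))
  }
  # tests 4 and 5 share the alternative: A | E categorical plus
  # B | E, A ~ N(nu_E + rho A, sB)
  alt45 <- function(p) {
    mu <- p[1:k]; nu <- p[(k + 1):(2 * k)]
    lsA <- p[2 * k + 1]; lsB <- p[2 * k + 2]; r <- p[2 * k + 3]
    ll_cat(A, mu, lsA) +
      sum(stats::dnorm(B, nu[idx] + r * A, exp(lsB), log = TRUE))
  }
  la <- ll_maximize(alt45, c(mu0A + 0.05, nu0 - 0.05, 0.1, 0.1, 0.1))
  if (test_id == 4L) {
    nul <- function(p) ll_cat(A, p[1:k], p[k + 1]) +
      sum(stats::dnorm(B, p[k + 2], exp(p[k + 3]), log = TRUE))
    return(la - ll_maximize(nul, c(mu0A + 0.05, 0.1, 0.05, 0.1)))
  }
  if (test_id == 5L) {
    nul <- function(p) ll_cat(A, p[1:k], p[k + 1]) +
      ll_cat(B, p[(k + 2):(2 * k + 1)], p[2 * k + 2])
    return(la - ll_maximize(nul, c(mu0A + 0.05, 0.1, nu0 - 0.05, 0.1)))
  }
  stop("unknown test_id")
}

closed_llr <- function(test_id, E, A, B = NULL) {
  switch(as.character(test_id),
         "0" = llr_correlation(A, B),
         "1" = llr_primary(E, A),
         "2" = llr_secondary(E, B),
         "3" = llr_independence(E, A, B),
         "4" = llr_relevance(E, A, B),
         "5" = llr_controlled(E, A, B))
}

# Exhaustive pairwise-comparison AUROC (midrank ties).
auroc_oracle <- function(scores, labels) {
  sp <- scores[as.logical(labels)]
  sn <- scores[!as.logical(labels)]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Quadrature AUPR oracle: trapezoid integration of the nonlinearly
# interpolated precision over every achievable segment.
aupr_oracle <- function(scores, labels, m = 20001L) {
  labels <- as.logical(labels)
  P <- sum(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)
  tp <- c(0, cumsum(y)[last]); fp <- c(0, cumsum(!y)[last])
  area <- 0
  for (k in seq_len(length(tp) - 1L)) {
    dtp <- tp[k + 1L] - tp[k]
    if (dtp == 0) next
    sl <- (fp[k + 1L] - fp[k]) / dtp
    xs <- seq(0, dtp, length.out = m)
    prec <- (tp[k] + xs) / (tp[k] + fp[k] + xs * (1 + sl))
    prec[!is.finite(prec)] <- 1 / (1 + sl)  # 0/0 limit at the origin
    area <- area + sum((prec[-1L] + prec[-m]) / 2) * (dtp / (m - 1L))
  }
  area / P
}

# Mixture of null draws and genuine-effect secondary-test statistics for
# posterior-calibration checks: returns LLR/n values, truth flags and
# the null spec. Effect sizes are far-shifted relative to the null.
make_llr_mixture <- function(n_items, pi0, n = 300L,
                             beta_range = c(0.4, 0.9)) {
  repeat {
    E <- encode_genotypes(stats::rbinom(n, 2L, 0.3))
    if (E$n_v == 3L) break
  }
  A <- supernormalize(stats::rnorm(n) + E$values)
  nn <- round(n_items * pi0)
  na <- n_items - nn
  bet <- stats::runif(na, beta_range[1], beta_range[2])
  Bm <- rbind(std_rows(matrix(stats::rnorm(nn * n), nn)),
              std_rows(matrix(stats::rnorm(na * n), na) +
                         bet %o% (E$values - mean(E$values))))
  z <- llr_profile_batch(E, A, Bm)[, "llr2"] / n
  list(z = z, truth = c(rep(FALSE, nn), rep(TRUE, na)),
       spec = null_spec(2L, n, E$n_v))
}

# Null LLR/n replicates for one test, vectorized over replicates.
simulate_null_llr <- function(test_id, n, n_v, R, rho = 0.5) {
  cats <- seq_len(n_v) - 1L
  repeat {
    ev <- sample(rep(cats, length.out = n))
    E <- encode_genotypes(ev)
    if (E$n_v == n_v) break
  }
  A <- supernormalize(stats::rnorm(n) + E$values)
  Bt <- matrix(stats::rnorm(R * n), R)
  if (test_id == 3L) {
    # chain null: B = rho A + noise, then re-standardized
    Bt <- rho * matrix(A, R, n, byrow = TRUE) + sqrt(1 - rho^2) * Bt
  } else if (test_id == 5L) {
    # genotype-only null: B = nu_E + sigma noise, then re-standardized
    nu <- seq(-0.5, 0.5, length.out = n_v)[match(E$values, cats)]
    Bt <- matrix(nu, R, n, byrow = TRUE) + 0.8 * Bt
  }
  Bm <- std_rows(Bt)
  llr_profile_batch(E, A, Bm)[, paste0("llr", test_id)] / n
}
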