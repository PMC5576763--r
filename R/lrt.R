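# Closed-form log-likelihood ratios for the six tests between an eQTL E,
# its cis-gene A and a candidate target B. All formulas assume A and B are
# supernormalized (zero mean, unit biased variance), which makes the MLE
# variance expressions below exact; raw input is refused.

# Any log argument below this is clamped so rho = +-1 and zero-residual
# inputs yield large finite LLRs instead of NaN/Inf.
.llr_eps <- 1e-300

check_supernormalized <- function(x, name = "input", tol = 1e-6) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop(name, " contains missing or non-finite values", call. = FALSE)
  }
  if (abs(mean(x)) > tol || abs(mean(x^2) - 1) > tol) {
    stop(name, " is not supernormalized (mean 0, biased variance 1 required)",
         call. = FALSE)
  }
  invisible(TRUE)
}

clamp_log <- function(x) log(pmax(x, .llr_eps))

# Per-genotype sufficient statistics of one supernormalized vector:
# group means and sigma^2 = 1 - sum_j (n_j/n) mean_j^2.
group_stats <- function(E, x) {
  mu <- vapply(split(x, E$values), mean, numeric(1))
  w <- E$n_j / E$n
  list(mu = mu, w = w, sigma2 = 1 - sum(w * mu^2))
}

#' Correlation-test log-likelihood ratio
#'
#' LLR of a bivariate-normal alternative (A and B correlated) against the
#' null of independence: `-(n/2) log(1 - rho^2)` with
#' `rho = (1/n) sum A_i B_i`.
#'
#' @param A,B Supernormalized numeric vectors of equal length (n >= 4).
#' @return Non-negative scalar LLR in nats.
#' @export
llr_correlation <- function(A, B) {
  if (length(A) != length(B)) {
    stop("A and B must have equal length", call. = FALSE)
  }
  check_supernormalized(A, "A")
  check_supernormalized(B, "B")
  n <- length(A)
  rho <- mean(A * B)
  -(n / 2) * clamp_log(1 - rho^2)
}

#' Primary (linkage) test log-likelihood ratio
#'
#' Tests E -> A: a genotype-categorical mean model for A against the
#' genotype-independent standard normal null. Statistic
#' `-(n/2) log sigma_A^2` with `sigma_A^2 = 1 - sum_j (n_j/n) mu_j^2`.
#'
#' @param E Genotype vector (raw integers or [encode_genotypes()] output)
#'   with at least two categories present.
#' @param A Supernormalized numeric vector.
#' @return Non-negative scalar LLR in nats.
#' @export
llr_primary <- function(E, A) {
  E <- as_genotype_vector(E)
  if (E$n != length(A)) stop("E and A must have equal length", call. = FALSE)
  if (E$n_v < 2L) {
    stop("degenerate genotype: only one category present", call. = FALSE)
  }
  check_supernormalized(A, "A")
  gs <- group_stats(E, A)
  -(E$n / 2) * clamp_log(gs$sigma2)
}

#' Secondary (linkage) test log-likelihood ratio
#'
#' Identical in form to [llr_primary()] but applied to the candidate target
#' B; verifies that E regulates B (directly or indirectly).
#'
#' @inheritParams llr_primary
#' @param B Supernormalized numeric vector.
#' @return Non-negative scalar LLR in nats.
#' @export
llr_secondary <- function(E, B) llr_primary(E, B)

# Shared sufficient statistics for the trivariate tests.
triple_stats <- function(E, A, B) {
  ga <- group_stats(E, A)
  gb <- group_stats(E, B)
  n <- E$n
  rho <- mean(A * B)
  sigmaAB <- 1 - sum(ga$w * ga$mu * gb$mu)
  list(n = n, rho = rho,
       sigmaA2 = ga$sigma2, sigmaB2 = gb$sigma2, sigmaAB = sigmaAB,
       # determinant of the per-genotype-centered covariance of (A, B)
       den = ga$sigma2 * gb$sigma2 - (rho + sigmaAB - 1)^2)
}

validate_triple <- function(E, A, B) {
  E <- as_genotype_vector(E)
  if (E$n != length(A) || E$n != length(B)) {
    stop("E, A and B must have equal length", call. = FALSE)
  }
  if (E$n_v < 2L) {
    stop("degenerate genotype: only one category present", call. = FALSE)
  }
  check_supernormalized(A, "A")
  check_supernormalized(B, "B")
  E
}

#' Conditional independence test log-likelihood ratio
#'
#' Compares the saturated model (per-genotype bivariate normal for (A, B))
#' against the causal chain E -> A -> B. Small values support the chain,
#' i.e. that E acts on B only through A.
#'
#' @inheritParams llr_primary
#' @param B Supernormalized numeric vector.
#' @return Non-negative scalar LLR in nats.
#' @export
llr_independence <- function(E, A, B) {
  E <- validate_triple(E, A, B)
  s <- triple_stats(E, A, B)
  -(s$n / 2) * clamp_log(s$den) + (s$n / 2) * clamp_log(s$sigmaA2) +
    (s$n / 2) * clamp_log(1 - s$rho^2)
}

#' Relevance test log-likelihood ratio
#'
#' Tests whether B depends on (E, A) jointly: the alternative regresses B
#' on genotype categories plus A linearly; the null leaves B independent.
#' Retains power on weak regulations where the secondary test alone fails.
#'
#' @inheritParams llr_independence
#' @return Non-negative scalar LLR in nats.
#' @export
llr_relevance <- function(E, A, B) {
  E <- validate_triple(E, A, B)
  s <- triple_stats(E, A, B)
  -(s$n / 2) * clamp_log(s$den) + (s$n / 2) * clamp_log(s$sigmaA2)
}

#' Controlled test log-likelihood ratio
#'
#' Tests whether the A-B correlation survives controlling for E, i.e. that
#' E does not regulate A and B independently (pure pleiotropy). The
#' alternative adds the A term to the genotype-only model of B.
#'
#' @inheritParams llr_independence
#' @return Non-negative scalar LLR in nats.
#' @export
llr_controlled <- function(E, A, B) {
  E <- validate_triple(E, A, B)
  s <- triple_stats(E, A, B)
  -(s$n / 2) * clamp_log(s$den) +
    (s$n / 2) * clamp_log(s$sigmaA2 * s$sigmaB2)
}

#' All six log-likelihood ratios for one (E, A, B) triple
#'
#' @inheritParams llr_independence
#' @return A list of class `"llr_profile"` with elements `llr0`...`llr5`
#'   (nats), `n` and `n_v`.
#' @export
llr_profile <- function(E, A, B) {
  E <- validate_triple(E, A, B)
  out <- llr_profile_batch(E, A, matrix(B, nrow = 1L))
  structure(
    list(llr0 = unname(out[1L, "llr0"]), llr1 = unname(out[1L, "llr1"]),
         llr2 = unname(out[1L, "llr2"]), llr3 = unname(out[1L, "llr3"]),
         llr4 = unname(out[1L, "llr4"]), llr5 = unname(out[1L, "llr5"]),
         n = E$n, n_v = E$n_v),
    class = "llr_profile"
  )
}

#' @export
print.llr_profile <- function(x, ...) {
  cat(sprintf(
    "<llr_profile> n = %d, n_v = %d\n  llr0..llr5: %s\n", x$n, x$n_v,
    paste(formatC(unlist(x[paste0("llr", 0:5)]), digits = 4, format = "g"),
          collapse = "  ")))
  invisible(x)
}

#' Batched log-likelihood ratios of one (E, A) against many B
#'
#' Computes all six LLRs for one anchored pair against every row of a B
#' matrix in a single pass from three inner products (sum A_i B_i,
#' per-genotype sums of B, and the group means), which is what makes
#' genome-scale scans feasible.
#'
#' @inheritParams llr_primary
#' @param Bmat Numeric matrix of supernormalized rows (candidates x
#'   samples).
#' @return Numeric matrix (`nrow(Bmat)` x 6) with columns `llr0`...`llr5`;
#'   `llr1` (which does not involve B) is repeated down its column.
#' @export
llr_profile_batch <- function(E, A, Bmat) {
  E <- as_genotype_vector(E)
  if (!is.matrix(Bmat)) Bmat <- matrix(Bmat, nrow = 1L)
  if (E$n != length(A) || E$n != ncol(Bmat)) {
    stop("sample counts of E, A and Bmat disagree", call. = FALSE)
  }
  if (E$n_v < 2L) {
    stop("degenerate genotype: only one category present", call. = FALSE)
  }
  n <- E$n
  ga <- group_stats(E, A)
  w <- ga$w
  # group-mean operator: n x n_v matrix with 1/n_j in category columns
  cats <- as.integer(names(E$n_j))
  Gm <- vapply(seq_along(cats), function(k) {
    v <- numeric(n)
    v[E$values == cats[k]] <- 1 / E$n_j[k]
    v
  }, numeric(n))
  rho <- as.numeric(Bmat %*% A) / n
  nu <- Bmat %*% Gm                       # per-candidate group means of B
  sigmaB2 <- 1 - as.numeric(nu^2 %*% w)
  sigmaAB <- 1 - as.numeric(nu %*% (w * ga$mu))
  den <- ga$sigma2 * sigmaB2 - (rho + sigmaAB - 1)^2

  llr0 <- -(n / 2) * clamp_log(1 - rho^2)
  llr1 <- rep(-(n / 2) * clamp_log(ga$sigma2), nrow(Bmat))
  llr2 <- -(n / 2) * clamp_log(sigmaB2)
  lden <- clamp_log(den)
  llr4 <- -(n / 2) * lden + (n / 2) * clamp_log(ga$sigma2)
  llr3 <- llr4 + (n / 2) * clamp_log(1 - rho^2)
  llr5 <- -(n / 2) * lden + (n / 2) * clamp_log(ga$sigma2 * sigmaB2)
  cbind(llr0 = llr0, llr1 = llr1, llr2 = llr2,
        llr3 = llr3, llr4 = llr4, llr5 = llr5)
}
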