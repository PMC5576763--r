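# The D(k1, k2) distribution family: the law of Z = -1/2 log(1 - Y) with
# Y ~ Beta(k1/2, k2/2). For every test here, LLR/n follows some member of
# this family under the null hypothesis, which is what makes p-values and
# null densities analytical (no permutations needed).

#' Null-distribution parameters for a test
#'
#' Maps a test id and the sample/genotype-category counts to the (k1, k2)
#' parameters of the D distribution followed by LLR/n under that test's
#' null hypothesis:
#' test 0: D(1, n-2); tests 1, 2: D(n_v-1, n-n_v); test 3:
#' D(n_v-1, n-n_v-1); test 4: D(n_v, n-n_v-1); test 5: D(1, n-n_v-1).
#'
#' @param test_id Integer 0-5 (0 correlation, 1 primary, 2 secondary,
#'   3 conditional independence, 4 relevance, 5 controlled).
#' @param n Sample count (>= 4).
#' @param n_v Number of genotype categories present (>= 2 for tests 1-5;
#'   ignored for test 0).
#' @return An object of class `"null_spec"`: list with `test_id`, `k1`,
#'   `k2`.
#' @examples
#' null_spec(0, n = 100)        # D(1, 98)
#' null_spec(3, n = 100, n_v = 3)  # D(2, 96)
#' @export
null_spec <- function(test_id, n, n_v = NULL) {
  if (!test_id %in% 0:5) stop("test_id must be in 0..5", call. = FALSE)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (test_id != 0) {
    if (is.null(n_v)) stop("n_v is required for tests 1-5", call. = FALSE)
    if (n_v < 2) stop("tests 1-5 require n_v >= 2", call. = FALSE)
  }
  k <- switch(as.character(test_id),
    "0" = c(1, n - 2),
    "1" = c(n_v - 1, n - n_v),
    "2" = c(n_v - 1, n - n_v),
    "3" = c(n_v - 1, n - n_v - 1),
    "4" = c(n_v, n - n_v - 1),
    "5" = c(1, n - n_v - 1)
  )
  if (any(k <= 0)) {
    stop(sprintf(
      "test %d is inapplicable at n = %d, n_v = %s (k1 = %g, k2 = %g)",
      test_id, n, if (is.null(n_v)) "NA" else n_v, k[1], k[2]),
      call. = FALSE)
  }
  structure(list(test_id = test_id, k1 = k[1], k2 = k[2]),
            class = "null_spec")
}

#' @export
print.null_spec <- function(x, ...) {
  cat(sprintf("<null_spec> test %d: LLR/n ~ D(%g, %g)\n",
              x$test_id, x$k1, x$k2))
  invisible(x)
}

as_null_spec <- function(spec) {
  if (!inherits(spec, "null_spec")) {
    stop("spec must be created with null_spec()", call. = FALSE)
  }
  spec
}

#' Density of the D(k1, k2) null distribution
#'
#' For z > 0: `2 / B(k1/2, k2/2) * (1 - exp(-2 z))^(k1/2 - 1) *
#' exp(-k2 z)`; zero for z <= 0.
#'
#' @param z Numeric vector of LLR/n values.
#' @param spec A [null_spec()] object.
#' @return Density values.
#' @export
d_pdf <- function(z, spec) {
  spec <- as_null_spec(spec)
  out <- numeric(length(z))
  pos <- z > 0
  zp <- z[pos]
  # log-scale for numerical stability at large k2
  out[pos] <- exp(log(2) - lbeta(spec$k1 / 2, spec$k2 / 2) +
                    (spec$k1 / 2 - 1) * log1p(-exp(-2 * zp)) -
                    spec$k2 * zp)
  out
}

#' Survival function of the D(k1, k2) null distribution
#'
#' Tail probability P(Z > z), i.e. the p-value of an observed LLR/n value.
#' Computed from the regularized incomplete beta function at
#' `y = 1 - exp(-2 z)`.
#'
#' @inheritParams d_pdf
#' @return Tail probabilities in [0, 1]; 1 for z <= 0.
#' @export
d_sf <- function(z, spec) {
  spec <- as_null_spec(spec)
  out <- rep(1, length(z))
  pos <- z > 0
  out[pos] <- stats::pbeta(-expm1(-2 * z[pos]), spec$k1 / 2, spec$k2 / 2,
                           lower.tail = FALSE)
  out
}

#' Cumulative distribution function of D(k1, k2)
#' @inheritParams d_pdf
#' @return P(Z <= z).
#' @export
d_cdf <- function(z, spec) 1 - d_sf(z, spec)

#' Quantile function of D(k1, k2)
#' @param p Probabilities.
#' @param spec A [null_spec()] object.
#' @return Quantiles z with P(Z <= z) = p.
#' @export
d_quantile <- function(p, spec) {
  spec <- as_null_spec(spec)
  -0.5 * log1p(-stats::qbeta(p, spec$k1 / 2, spec$k2 / 2))
}

#' Draw from the D(k1, k2) null distribution
#'
#' @param spec A [null_spec()] object.
#' @param count Number of draws.
#' @param seed Optional integer seed; when given, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of positive draws.
#' @export
d_sample <- function(spec, count, seed = NULL) {
  spec <- as_null_spec(spec)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  y <- stats::rbeta(count, spec$k1 / 2, spec$k2 / 2)
  -0.5 * log1p(-y)
}
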