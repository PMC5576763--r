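# Empirical-Bayes conversion of observed LLR/n values into posterior
# probabilities. The observed statistics form a mixture of null and
# alternative hypotheses; the null density is analytical (D family), the
# mixture density is estimated by a smoothed histogram, and the null
# proportion pi0 is fixed by aligning the two near LLR -> 0+, where all
# test cases are assumed null. The resulting posteriors are empirical
# local precision estimates.

#' Estimate the null proportion of an LLR sample
#'
#' Aligns the analytical null density with the observed mixture over the
#' lowest-decile region of the statistic's range: pi0 is the ratio of the
#' observed probability mass below `max(values)/10` to the null mass of
#' the same region, capped at 1. This implements the assumption that as
#' LLR approaches zero from above all test cases come from the null.
#'
#' @param values Non-negative LLR/n values (at least 100 recommended; with
#'   fewer, pool across anchored pairs instead).
#' @param spec The [null_spec()] of the test that produced the values.
#' @return Estimated null proportion in [0, 1].
#' @export
estimate_pi0 <- function(values, spec) {
  spec <- as_null_spec(spec)
  values <- values[is.finite(values)]
  if (length(values) == 0L || max(values) - min(values) <= 0) {
    stop("degenerate LLR sample: all values identical", call. = FALSE)
  }
  q <- max(values) / 10
  null_mass <- d_cdf(q, spec)
  if (null_mass <= 0) return(1)
  min(1, mean(values <= q) / null_mass)
}

#' Build the LLR-to-posterior lookup for one test
#'
#' Bins LLR/n on an equal-width histogram over `[0, max]` (bin count
#' `max(100, floor(sqrt(N)))`), smooths the observed density and the
#' discretized null density identically with a 3-bin moving average
#' applied twice (smoothing only the observed side biases the ratio
#' wherever the null density falls steeply across bins, which breaks
#' posterior calibration), and computes the per-bin posterior of the
#' selected hypothesis: `1 - pi0 p0 / p` for the alternative-direction
#' tests (0, 1, 2, 4, 5) and `pi0 p0 / p` for the conditional-independence
#' test (3), clipped to [0, 1] and monotonized (cumulative max, resp. min)
#' in the LLR direction. Values outside the histogram range map to the
#' nearest edge bin.
#'
#' @inheritParams estimate_pi0
#' @param n_bins Optional bin-count override.
#' @return An object of class `"posterior_map"`: list with `edges`,
#'   `posterior` (per bin), `pi0`, `direction` (`"increasing"` or
#'   `"decreasing"`), and `spec`.
#' @export
build_posterior_map <- function(values, spec, n_bins = NULL) {
  spec <- as_null_spec(spec)
  values <- values[is.finite(values)]
  n <- length(values)
  pi0 <- estimate_pi0(values, spec)
  if (is.null(n_bins)) n_bins <- max(100L, floor(sqrt(n)))
  zmax <- max(values)
  edges <- seq(0, zmax, length.out = n_bins + 1L)
  dz <- edges[2L] - edges[1L]
  counts <- tabulate(pmin(pmax(findInterval(values, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins),
                     nbins = n_bins)
  phat <- counts / (n * dz)
  phat <- smooth_ma3(smooth_ma3(phat))
  p0 <- smooth_ma3(smooth_ma3(diff(d_cdf(edges, spec)) / dz))
  # Poisson-aware regularized ratio of expected null counts to observed
  # counts. The raw density ratio is pure noise wherever the expected
  # null count per bin is of order one: chance clusters of 2-3
  # observations against an expected 0.2-3 would receive posteriors of
  # 0.4-0.8 even on pure-null input. Buffering the expected count by
  # ~2.5 of its own Poisson standard deviations suppresses exactly those
  # bins, while bins where the null expects essentially nothing (e -> 0)
  # keep full evidence strength: a single observation there is
  # conclusive, which is what preserves isolated strong targets.
  k_obs <- n * dz * phat
  k_null <- pi0 * n * dz * p0
  ratio <- (k_null + 2.5 * sqrt(k_null) + 0.01) / (k_obs + 0.01)
  if (spec$test_id == 3L) {
    post <- cummin(pmin(pmax(ratio, 0), 1))
    direction <- "decreasing"
  } else {
    post <- cummax(pmin(pmax(1 - ratio, 0), 1))
    direction <- "increasing"
  }
  structure(list(edges = edges, posterior = post, pi0 = pi0,
                 direction = direction, spec = spec),
            class = "posterior_map")
}

# 3-bin moving average with shortened window at the edges.
smooth_ma3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  y <- x
  y[1L] <- mean(x[1:2])
  y[n] <- mean(x[(n - 1L):n])
  y[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  y
}

#' @export
print.posterior_map <- function(x, ...) {
  cat(sprintf("<posterior_map> test %d, %d bins, pi0 = %.3f, %s\n",
              x$spec$test_id, length(x$posterior), x$pi0, x$direction))
  invisible(x)
}

#' Look up posteriors for LLR/n values
#'
#' @param map A [build_posterior_map()] result.
#' @param values LLR/n values (NA passes through as NA).
#' @return Posterior probabilities in [0, 1].
#' @export
posterior_lookup <- function(map, values) {
  nb <- length(map$posterior)
  idx <- findInterval(values, map$edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  out[ok] <- map$posterior[idx[ok]]
  out
}

#' Convert a matrix of LLR/n values into posterior probabilities
#'
#' Rows index anchored (E, A) pairs, columns index candidate targets B.
#' In `"per-pair"` mode each row gets its own mixture decomposition (the
#' recommended setting when thousands of candidates are tested per pair,
#' as it accounts for different rates of alternatives per regulator); rows
#' with fewer than `min_targets` finite values fall back to the pooled map
#' with a logged warning. In `"pooled"` mode one decomposition is shared.
#'
#' @param llr_matrix Numeric matrix of LLR/n values; NA entries (e.g. the
#'   self-pair diagonal) propagate as NA.
#' @param spec A single [null_spec()] shared by all rows, or a list of one
#'   spec per row (genotype category counts may differ between eQTLs).
#' @param mode `"per-pair"` or `"pooled"`.
#' @param min_targets Minimum finite values per row for per-pair mode.
#' @return Matrix of posteriors, same shape and dimnames as `llr_matrix`.
#' @export
posteriors <- function(llr_matrix, spec, mode = c("per-pair", "pooled"),
                       min_targets = 100L) {
  mode <- match.arg(mode)
  if (!is.matrix(llr_matrix)) llr_matrix <- matrix(llr_matrix, nrow = 1L)
  specs <- if (inherits(spec, "null_spec")) {
    rep(list(spec), nrow(llr_matrix))
  } else {
    stopifnot(length(spec) == nrow(llr_matrix))
    spec
  }
  out <- llr_matrix
  out[] <- NA_real_
  pooled_maps <- new.env(parent = emptyenv())
  pooled_map_for <- function(s) {
    key <- sprintf("%d_%g_%g", s$test_id, s$k1, s$k2)
    if (is.null(pooled_maps[[key]])) {
      rows <- vapply(specs, function(x) identical(unclass(x), unclass(s)),
                     logical(1))
      pooled_maps[[key]] <- build_posterior_map(
        as.numeric(llr_matrix[rows, , drop = FALSE]), s)
    }
    pooled_maps[[key]]
  }
  n_fallback <- 0L
  for (i in seq_len(nrow(llr_matrix))) {
    row <- llr_matrix[i, ]
    n_ok <- sum(is.finite(row))
    if (mode == "pooled") {
      map <- pooled_map_for(specs[[i]])
    } else if (n_ok >= min_targets) {
      map <- build_posterior_map(row[is.finite(row)], specs[[i]])
    } else {
      n_fallback <- n_fallback + 1L
      map <- pooled_map_for(specs[[i]])
    }
    out[i, ] <- posterior_lookup(map, row)
  }
  if (n_fallback > 0L) {
    eq_log("posterior", "WARN", sprintf(
      "%d of %d rows have fewer than %d candidates; falling back to pooled posterior",
      n_fallback, nrow(llr_matrix), min_targets))
  }
  out
}
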