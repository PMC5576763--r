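# Generators: (a) the measurement-error causal model E -> A(t) -> B with
# A(t) -> A and its p-value grid scan; (b) a desk-scale synthetic eQTL
# network with known ground truth and confounding labels.

#' Configuration of the measurement-error causal model
#'
#' The ground-truth model is E -> A(t) -> B with A(t) -> A: E is the
#' exactly measured genotype, A(t) the unobservable true expression of
#' gene A, A its noisy measurement, and B a measured target.
#'
#' @param n Samples (default 300).
#' @param maf Minor allele frequency in (0, 1) of the monoallelic genotype
#'   (default 0.1).
#' @param sigmaA1_sq Variance of A(t) beyond E (default 1: as much
#'   trans/biological variance as eQTL-explained variance, which is 1
#'   after genotype standardization).
#' @param sigmaA2_sq Measurement-noise variance of A around A(t)
#'   (default 1).
#' @param sigmaB_sq B's residual variance around the standardized A(t)
#'   (default 2, i.e. one third of B's total variance comes from A(t)).
#' @param seed Integer seed.
#' @return A `me_config` list.
#' @export
me_config <- function(n = 300L, maf = 0.1, sigmaA1_sq = 1,
                      sigmaA2_sq = 1, sigmaB_sq = 2, seed = 0L) {
  stopifnot(n >= 4, maf > 0, maf < 1,
            sigmaA1_sq > 0, sigmaA2_sq > 0, sigmaB_sq > 0)
  structure(list(n = as.integer(n), maf = maf, sigmaA1_sq = sigmaA1_sq,
                 sigmaA2_sq = sigmaA2_sq, sigmaB_sq = sigmaB_sq,
                 seed = as.integer(seed)),
            class = "me_config")
}

# Zero-mean unit-variance scaling (population variance); the simulation
# uses plain normalization, not the rank-based transform.
tilde <- function(x) {
  s2 <- mean((x - mean(x))^2)
  if (s2 <= 0) return(rep(0, length(x)))
  (x - mean(x)) / sqrt(s2)
}

#' Simulate one (E, A, B) triple under the measurement-error model
#'
#' Per sample i: `E_i ~ Bernoulli(maf)`, `A(t)_i ~ N(tilde(E)_i,
#' sigmaA1_sq)`, `A_i ~ N(A(t)_i, sigmaA2_sq)`, `B_i ~ N(tilde(A(t))_i,
#' sigmaB_sq)`, where `tilde` rescales a variable to zero mean and unit
#' variance. A(t) is returned for bookkeeping only and must never reach
#' inference code.
#'
#' @param config A [me_config()].
#' @param use_seed Set the RNG from `config$seed` (default TRUE; the grid
#'   scan manages seeding itself and passes FALSE).
#' @return List with `E` (0/1 integers), `A_true`, `A`, `B`, and
#'   `degenerate` (TRUE when all genotypes came out equal, in which case
#'   the genotype carries no signal and downstream tests must reject it).
#' @export
simulate_triple <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "me_config"))
  if (use_seed) set.seed(config$seed)
  n <- config$n
  E <- stats::rbinom(n, 1L, config$maf)
  degenerate <- length(unique(E)) < 2L
  Et <- tilde(E)
  A_true <- stats::rnorm(n, Et, sqrt(config$sigmaA1_sq))
  A <- stats::rnorm(n, A_true, sqrt(config$sigmaA2_sq))
  B <- stats::rnorm(n, tilde(A_true), sqrt(config$sigmaB_sq))
  list(E = E, A_true = A_true, A = A, B = B, degenerate = degenerate)
}

#' P-value grid scan over measurement-error strengths
#'
#' Varies `sigmaA1_sq` (x) and `sigmaA2_sq` (y) over a log-spaced grid,
#' simulates the ground-truth chain at every tile, and records the
#' analytical p-values of tests 1-5 computed on the normalized observed
#' data. Tiles whose primary (E -> A) p-value exceeds `eqtl_alpha` are
#' masked: they carry no usable eQTL. The same initial seed is used for
#' every tile so that adjacent tiles differ only through the parameters.
#' Under the true chain model, small test-3 p-values are false rejections
#' of conditional independence, whereas small p-values of tests 2, 4, 5
#' are true positives.
#'
#' @param base A [me_config()]; its `sigmaA1_sq`/`sigmaA2_sq` are
#'   overridden tile by tile.
#' @param grid_points Grid resolution per axis (default 25; use 100 to
#'   match a full-scale scan).
#' @param sigma_range Range of both scanned variances (default
#'   `c(1e-2, 1e2)`).
#' @param replicates Simulations per tile; reported p-values are per-tile
#'   medians over replicates (default 1).
#' @param eqtl_alpha Primary-test masking threshold (default 1e-6).
#' @return Long data frame: `sigmaA1_sq`, `sigmaA2_sq`, `test_id` (1-5),
#'   `p_value`, `masked`.
#' @export
grid_scan <- function(base, grid_points = 25L, sigma_range = c(1e-2, 1e2),
                      replicates = 1L, eqtl_alpha = 1e-6) {
  stopifnot(inherits(base, "me_config"), grid_points >= 2L,
            replicates >= 1L)
  sig <- 10^seq(log10(sigma_range[1]), log10(sigma_range[2]),
                length.out = grid_points)
  out <- vector("list", grid_points^2)
  k <- 0L
  for (sa1 in sig) {
    for (sa2 in sig) {
      cfg <- me_config(n = base$n, maf = base$maf, sigmaA1_sq = sa1,
                       sigmaA2_sq = sa2, sigmaB_sq = base$sigmaB_sq,
                       seed = base$seed)
      set.seed(base$seed)
      pv <- matrix(NA_real_, replicates, 5L)
      for (r in seq_len(replicates)) {
        tr <- simulate_triple(cfg, use_seed = FALSE)
        if (tr$degenerate) next
        pv[r, ] <- triple_pvalues(tr)
      }
      med <- apply(pv, 2L, stats::median, na.rm = TRUE)
      k <- k + 1L
      out[[k]] <- data.frame(
        sigmaA1_sq = sa1, sigmaA2_sq = sa2, test_id = 1:5,
        p_value = med,
        masked = !is.finite(med[1L]) || med[1L] > eqtl_alpha)
    }
  }
  do.call(rbind, out)
}

# Analytical p-values of tests 1-5 for one simulated triple (plain
# z-normalization, as in the simulation study).
triple_pvalues <- function(tr) {
  E <- encode_genotypes(tr$E)
  if (E$n_v < 2L) return(rep(NA_real_, 5L))
  A <- znormalize(tr$A)
  B <- znormalize(tr$B)
  prof <- llr_profile_batch(E, A, matrix(B, nrow = 1L)) / E$n
  vapply(1:5, function(t)
    d_sf(prof[1L, paste0("llr", t)], null_spec(t, E$n, E$n_v)),
    numeric(1))
}

#' Configuration of the synthetic eQTL-network generator
#'
#' @param n_genes Number of genes (default 1000); every gene carries one
#'   biallelic cis-eQTL.
#' @param n_samples Samples (default 300).
#' @param maf Minor allele frequency of the eQTLs (default 0.3).
#' @param edge_density Probability that a gene directly regulates one
#'   downstream target (default 0.8, about 0.8 regulations per gene;
#'   base edges have out-degree at most one, so with
#'   `confounder_fraction = 0` no two genes share a direct upstream
#'   regulator and the confounded-pair labels are empty).
#' @param confounder_fraction Fraction of true edges that additionally
#'   receive a shared upstream regulator, confounding the pair
#'   (default 0.5: confounding treated as the rule, not the exception).
#' @param effect_size Magnitude of both the cis-genotype effect and the
#'   edge coefficients, relative to unit residual noise (default 1).
#' @param noise_sd Residual noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return A `network_config` list.
#' @export
network_config <- function(n_genes = 1000L, n_samples = 300L, maf = 0.3,
                           edge_density = 0.8, confounder_fraction = 0.5,
                           effect_size = 1, noise_sd = 1, seed = 0L) {
  stopifnot(n_genes >= 3, n_samples >= 4, maf > 0, maf < 1,
            edge_density >= 0, edge_density <= 1,
            confounder_fraction >= 0, confounder_fraction <= 1,
            effect_size >= 0, noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), maf = maf,
                 edge_density = edge_density,
                 confounder_fraction = confounder_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Generate a synthetic eQTL network dataset with ground truth
#'
#' Builds a random DAG over genes in a fixed topological order, plants a
#' biallelic cis-eQTL on every gene, propagates expression linearly along
#' the edges with Gaussian noise, and labels every ordered gene pair as
#' confounded when the two genes share at least one direct upstream
#' regulator. A tunable fraction of true edges is deliberately given such
#' a shared regulator, which is the regime where the conditional
#' independence test loses true targets.
#'
#' @param config A [network_config()].
#' @return List with `expression` (genes x samples), `genotypes` (eQTLs x
#'   samples, values 0/1/2), `pairs` (eqtl, gene), `edges` (from, to),
#'   `confounded` (logical genes x genes matrix over ordered pairs), and
#'   `config`.
#' @export
generate_network_dataset <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  G <- config$n_genes
  n <- config$n_samples
  genes <- sprintf("G%04d", seq_len(G))
  eqtls <- sprintf("E%04d", seq_len(G))

  geno <- matrix(stats::rbinom(G * n, 2L, config$maf), nrow = G,
                 dimnames = list(eqtls, NULL))

  # adjacency over the topological order (edges only i -> j with i < j);
  # each source gene regulates at most one base target so that shared
  # upstream regulators come only from the explicit confounder mechanism
  adj <- matrix(FALSE, G, G)
  if (config$edge_density > 0) {
    for (i in seq_len(G - 1L)) {
      if (stats::runif(1) < config$edge_density) {
        j <- if (i == G - 1L) G else i + sample.int(G - i, 1L)
        adj[i, j] <- TRUE
      }
    }
  }
  # confound a fraction of the true edges with a shared upstream regulator
  base_edges <- which(adj, arr.ind = TRUE)
  if (nrow(base_edges) > 0 && config$confounder_fraction > 0) {
    pick <- which(stats::runif(nrow(base_edges)) <
                    config$confounder_fraction)
    for (k in pick) {
      i <- base_edges[k, 1L]; j <- base_edges[k, 2L]
      if (i > 1L) {
        c_ <- sample.int(i - 1L, 1L)
        adj[c_, i] <- TRUE
        adj[c_, j] <- TRUE
      }
    }
  }

  expr <- matrix(0, G, n, dimnames = list(genes, NULL))
  scaled <- matrix(0, G, n)  # standardized copies for propagation
  for (j in seq_len(G)) {
    cisv <- geno[j, ]
    x <- config$noise_sd * stats::rnorm(n)
    if (stats::sd(cisv) > 0) x <- x + config$effect_size * tilde(cisv)
    parents <- which(adj[, j])
    for (i in parents) {
      beta <- config$effect_size * stats::runif(1, 0.5, 1.5) *
        sample(c(-1, 1), 1L)
      x <- x + beta * scaled[i, ]
    }
    expr[j, ] <- x
    scaled[j, ] <- tilde(x)
  }

  ed <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = genes[ed[, 1L]], to = genes[ed[, 2L]],
                      stringsAsFactors = FALSE)
  confounded <- matrix(FALSE, G, G, dimnames = list(genes, genes))
  for (c_ in seq_len(G)) {
    ch <- which(adj[c_, ])
    if (length(ch) >= 2L) confounded[ch, ch] <- TRUE
  }
  diag(confounded) <- FALSE

  colnames(expr) <- colnames(geno) <- sprintf("S%03d", seq_len(n))
  list(expression = expr, genotypes = geno,
       pairs = data.frame(eqtl = eqtls, gene = genes,
                          stringsAsFactors = FALSE),
       edges = edges, confounded = confounded, config = config)
}
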