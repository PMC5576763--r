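# Composite causal scores and the dataset-level driver.

check_prob <- function(x, name) {
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE)) {
    stop(name, " contains entries outside [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Traditional causal score
#'
#' `PT = P1 P2 P3` with `P1 = 1` assumed for pre-validated eQTLs: the
#' chain E -> A -> B is called positive only when the secondary and
#' conditional-independence tests both support it. Precise on unconfounded
#' chains, but loses confounded or noisily measured true targets because
#' P3 collapses there.
#'
#' @param P2,P3 Posterior matrices of the secondary and conditional
#'   independence tests (entries in [0, 1], same shape).
#' @return Elementwise product, same shape.
#' @export
score_traditional <- function(P2, P3) {
  if (!identical(dim(P2), dim(P3)) && length(P2) != length(P3)) {
    stop("P2 and P3 shapes disagree", call. = FALSE)
  }
  check_prob(P2, "P2"); check_prob(P3, "P3")
  P2 * P3
}

#' Composite (confounder-robust) causal score
#'
#' `P = (P2 P5 + P4) / 2`. The first term requires E to regulate B and the
#' A-B correlation to survive controlling for E (tolerating hidden
#' confounders); the second keeps power on regulations too weak for the
#' secondary test, reducing to `P4 / 2` when `P2 = 0` (equal probability
#' to either causal direction).
#'
#' @param P2,P4,P5 Posterior matrices of the secondary, relevance and
#'   controlled tests.
#' @return Elementwise `(P2 * P5 + P4) / 2`, same shape.
#' @export
score_novel <- function(P2, P4, P5) {
  check_prob(P2, "P2"); check_prob(P4, "P4"); check_prob(P5, "P5")
  (P2 * P5 + P4) / 2
}

#' Run configuration for the inference driver
#'
#' @param mode Posterior estimation mode, `"per-pair"` or `"pooled"`.
#' @param min_targets Minimum candidates per pair for per-pair posteriors.
#' @param n_bins Optional histogram bin-count override.
#' @param normalization `"supernormalize"` (default) or `"znormalize"`.
#' @param seed Integer seed recorded in outputs (the pipeline itself is
#'   deterministic; the seed feeds any generator the caller pairs it with).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("per-pair", "pooled"), min_targets = 100L,
                       n_bins = NULL,
                       normalization = c("supernormalize", "znormalize"),
                       seed = 0L) {
  structure(list(mode = match.arg(mode),
                 min_targets = as.integer(min_targets),
                 n_bins = n_bins,
                 normalization = match.arg(normalization),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Infer causal scores for every anchored pair against all candidates
#'
#' The full pipeline: supernormalize the expression matrix once; for every
#' (eQTL E, cis-gene A) pair compute the batched log-likelihood ratios of
#' tests 0 and 2-5 against every other gene B; convert each test's LLR/n
#' values to posterior probabilities by the empirical-Bayes mixture
#' machinery; and assemble the composite scores. The primary test is not
#' scored (P1 = 1 is assumed for pre-validated eQTLs); its LLR and
#' analytical p-value are attached to the pair table as diagnostics.
#' Self-pairs (B = A) are never scored and carry NA.
#'
#' @param expression Numeric matrix, genes x samples, with gene row names.
#' @param genotypes Integer matrix, eQTLs x samples, with eQTL row names.
#' @param pairs Data frame with columns `eqtl` and `gene`: each row anchors
#'   one cis-gene A to its best eQTL E. IDs must exist in the matrices.
#' @param config A [run_config()].
#' @return An object of class `"score_set"`: list of matrices `P0`, `P2`,
#'   `P3`, `P4`, `P5`, `PT`, `P` (pairs x genes), the `pairs` table with
#'   diagnostics (`n_v`, `llr1`, `pvalue1`), `genes`, `n`, and `config`.
#' @export
infer_all <- function(expression, genotypes, pairs,
                      config = run_config()) {
  stopifnot(is.matrix(expression), is.matrix(genotypes),
            is.data.frame(pairs))
  if (is.null(rownames(expression)) || is.null(rownames(genotypes))) {
    stop("expression and genotype matrices need row names", call. = FALSE)
  }
  if (!all(c("eqtl", "gene") %in% names(pairs))) {
    stop("pairs must have columns 'eqtl' and 'gene'", call. = FALSE)
  }
  bad_e <- setdiff(pairs$eqtl, rownames(genotypes))
  bad_g <- setdiff(pairs$gene, rownames(expression))
  if (length(bad_e) || length(bad_g)) {
    stop("pairs reference unknown IDs: ",
         paste(c(bad_e, bad_g), collapse = ", "), call. = FALSE)
  }
  if (ncol(expression) != ncol(genotypes)) {
    stop("expression and genotypes disagree on sample count", call. = FALSE)
  }
  n <- ncol(expression)
  genes <- rownames(expression)
  sn <- supernormalize_matrix(expression, method = config$normalization)

  keep <- logical(nrow(pairs))
  Elist <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    E <- encode_genotypes(genotypes[pairs$eqtl[i], ])
    Elist[[i]] <- E
    keep[i] <- E$n_v >= 2L
    if (!keep[i]) {
      eq_log("infer", "WARN", sprintf(
        "pair %s -> %s dropped: eQTL has a single genotype category",
        pairs$eqtl[i], pairs$gene[i]))
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  Elist <- Elist[keep]
  np <- nrow(pairs)
  if (np == 0L) stop("no usable (eQTL, gene) pairs", call. = FALSE)

  tests <- c(0L, 2L, 3L, 4L, 5L)
  llr_n <- lapply(tests, function(t)
    matrix(NA_real_, np, length(genes),
           dimnames = list(pairs$gene, genes)))
  names(llr_n) <- paste0("t", tests)
  specs <- lapply(tests, function(t) vector("list", np))
  names(specs) <- names(llr_n)
  llr1 <- numeric(np)
  pv1 <- numeric(np)

  for (i in seq_len(np)) {
    E <- Elist[[i]]
    A <- sn[pairs$gene[i], ]
    prof <- llr_profile_batch(E, A, sn) / n
    self <- match(pairs$gene[i], genes)
    for (t in tests) {
      col <- prof[, paste0("llr", t)]
      col[self] <- NA_real_
      llr_n[[paste0("t", t)]][i, ] <- col
      specs[[paste0("t", t)]][[i]] <- null_spec(t, n, E$n_v)
    }
    llr1[i] <- prof[1L, "llr1"] * n
    pv1[i] <- d_sf(prof[1L, "llr1"], null_spec(1L, n, E$n_v))
  }

  post <- lapply(names(llr_n), function(nm)
    posteriors(llr_n[[nm]], specs[[nm]], mode = config$mode,
               min_targets = config$min_targets))
  names(post) <- names(llr_n)

  pairs$n_v <- vapply(Elist, `[[`, integer(1), "n_v")
  pairs$llr1 <- llr1
  pairs$pvalue1 <- pv1
  structure(
    list(P0 = post$t0, P2 = post$t2, P3 = post$t3, P4 = post$t4,
         P5 = post$t5,
         PT = score_traditional(post$t2, post$t3),
         P = score_novel(post$t2, post$t4, post$t5),
         pairs = pairs, genes = genes, n = n, config = config),
    class = "score_set"
  )
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf(
    "<score_set> %d anchored pairs x %d candidate genes (n = %d samples)\n",
    nrow(x$pairs), length(x$genes), x$n))
  cat("scores: P0 P2 P3 P4 P5 PT P  (self-pairs NA)\n")
  invisible(x)
}

#' Flatten a score set to a long table
#'
#' @param x A `score_set`.
#' @return Data frame with one row per scored (A, B) pair: `eqtl`, `A`,
#'   `B`, the five test posteriors and both composite scores.
#' @export
score_long <- function(x) {
  stopifnot(inherits(x, "score_set"))
  np <- nrow(x$pairs)
  ng <- length(x$genes)
  out <- data.frame(
    eqtl = rep(x$pairs$eqtl, ng),
    A = rep(x$pairs$gene, ng),
    B = rep(x$genes, each = np),
    P0 = as.numeric(x$P0), P2 = as.numeric(x$P2), P3 = as.numeric(x$P3),
    P4 = as.numeric(x$P4), P5 = as.numeric(x$P5),
    PT = as.numeric(x$PT), P = as.numeric(x$P),
    stringsAsFactors = FALSE
  )
  out[!is.na(out$P), , drop = FALSE]
}
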