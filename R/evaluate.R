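# Evaluation of ranked predictions against ground truth: AUROC, AUPR with
# the Davis-Goadrich nonlinear precision-recall interpolation, subsampled
# re-inference, and local precision of top predictions split by
# confounding status.

check_binary_labels <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  labels
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC with midrank tie handling, so
#' permuting equal-scored items cannot change the result.
#'
#' @param scores Numeric prediction scores (higher = more confident).
#' @param labels Binary ground-truth labels (TRUE/1 = real regulation).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  np <- as.numeric(sum(labels)); nn <- as.numeric(sum(!labels))
  if (np == 0 || nn == 0) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (Davis-Goadrich)
#'
#' Integrates precision over recall between achievable PR points (one per
#' distinct score value) using the nonlinear interpolation that is linear
#' in true-positive counts: between consecutive points, FP grows linearly
#' with TP, inducing the hyperbolic precision segment whose integral is
#' taken in closed form. Tie groups collapse into single achievable
#' points, so equal-scored permutations cannot change the result.
#'
#' @inheritParams auroc
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  P <- as.numeric(sum(labels))
  if (P == 0) stop("AUPR undefined: no positives", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # achievable points: cumulative (TP, FP) at the last item of each tie
  # group
  last <- cumsum(rle(s)$lengths)
  tp <- as.numeric(cumsum(y)[last])
  fp <- as.numeric(cumsum(!y)[last])
  tp <- c(0, tp); fp <- c(0, fp)
  area <- 0
  for (k in seq_len(length(tp) - 1L)) {
    dtp <- tp[k + 1L] - tp[k]
    if (dtp == 0) next
    b <- 1 + (fp[k + 1L] - fp[k]) / dtp
    cc <- tp[k] + fp[k]
    if (cc == 0) {
      area <- area + dtp / b
    } else {
      K <- (tp[k] - cc / b) / b
      area <- area + dtp / b + K * (log(cc + b * dtp) - log(cc))
    }
  }
  area / P
}

# Flatten a score_set's matrix for one score against a ground-truth edge
# table, returning aligned vectors of scores, labels and (optionally)
# confounding flags. Self-pairs (NA scores) are dropped.
score_eval_frame <- function(scores_mat, pairs, genes, edges,
                             confounded = NULL) {
  np <- nrow(scores_mat); ng <- length(genes)
  A <- rep(pairs$gene, ng)
  B <- rep(genes, each = np)
  s <- as.numeric(scores_mat)
  keep <- !is.na(s)
  lab_mat <- matrix(FALSE, ng, ng, dimnames = list(genes, genes))
  lab_mat[cbind(match(edges$from, genes), match(edges$to, genes))] <- TRUE
  lab <- lab_mat[cbind(match(A, genes), match(B, genes))]
  out <- data.frame(A = A[keep], B = B[keep], score = s[keep],
                    label = lab[keep], stringsAsFactors = FALSE)
  if (!is.null(confounded)) {
    out$confounded <- confounded[cbind(match(out$A, genes),
                                       match(out$B, genes))]
  }
  out
}

#' Evaluate a score set against ground-truth edges
#'
#' @param x A `score_set` from [infer_all()].
#' @param edges Data frame of true directed regulations (`from`, `to`).
#' @param which Score names to evaluate (default all).
#' @return Data frame with one row per score: `score`, `auroc`, `aupr`,
#'   `prevalence`.
#' @export
evaluate_scores <- function(x, edges,
                            which = c("P0", "P2", "P3", "P4", "P5",
                                      "PT", "P")) {
  stopifnot(inherits(x, "score_set"))
  rows <- lapply(which, function(w) {
    fr <- score_eval_frame(x[[w]], x$pairs, x$genes, edges)
    data.frame(score = w,
               auroc = auroc(fr$score, fr$label),
               aupr = aupr(fr$score, fr$label),
               prevalence = mean(fr$label),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subsampled re-inference
#'
#' Repeats k times: draw N samples without replacement, rerun the full
#' inference on the subset, and score the named metrics against the
#' ground truth. Returns the mean, standard deviation and standard error
#' over rounds; the mean summarizes average performance at that sample
#' size while the SD shows how individual subsamples scatter around it.
#'
#' @param expression,genotypes,pairs As for [infer_all()].
#' @param edges True directed regulations (`from`, `to`).
#' @param N Subsample size (<= total samples).
#' @param k Rounds (default 100).
#' @param seed Integer seed for the subsample draws.
#' @param config A [run_config()].
#' @param which Score names to track (default `"P"` and `"PT"`).
#' @return Data frame with columns `score`, `metric`, `mean`, `sd`, `se`,
#'   `N`, `k`.
#' @export
subsample_evaluate <- function(expression, genotypes, pairs, edges, N,
                               k = 100L, seed = 0L,
                               config = run_config(),
                               which = c("P", "PT")) {
  n <- ncol(expression)
  stopifnot(N >= 4, N <= n, k >= 1)
  set.seed(seed)
  res <- vector("list", k)
  for (r in seq_len(k)) {
    idx <- sample.int(n, N)
    ss <- infer_all(expression[, idx, drop = FALSE],
                    genotypes[, idx, drop = FALSE], pairs, config)
    ev <- evaluate_scores(ss, edges, which = which)
    res[[r]] <- ev
  }
  all_ev <- do.call(rbind, res)
  out <- list()
  for (w in which) {
    for (m in c("auroc", "aupr")) {
      v <- all_ev[all_ev$score == w, m]
      out[[length(out) + 1L]] <- data.frame(
        score = w, metric = m, mean = mean(v), sd = stats::sd(v),
        se = stats::sd(v) / sqrt(k), N = N, k = k,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Default rank-range bins (percent of all ranked pairs)
#' @return Numeric vector of bin edges in percent.
#' @export
default_rank_bins <- function() c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                                  1, 10, 100)

#' Local precision of top predictions, split by confounding
#'
#' Ranks all scored ordered pairs globally, cuts the ranking into
#' relative-rank ranges (default: top 0-0.01%, 0.01-0.02%, 0.02-0.05%,
#' 0.05-0.1%, 0.1-0.2%, 0.2-0.5%, 0.5-1%, 1-10%, 10-100%), splits every
#' range by whether the pair shares at least one direct upstream
#' regulator in the ground truth (confounded), and reports the local
#' precision (true regulations / pairs) plus counts per subgroup. Ties
#' are broken by stable input order after a seeded shuffle.
#'
#' @param scores Numeric scores of all ordered pairs.
#' @param labels Binary truth per pair.
#' @param confounded Logical flag per pair.
#' @param rank_bins Bin edges in percent (default [default_rank_bins()]).
#' @param seed Seed of the tie-break shuffle.
#' @return Data frame: `bin_lo`, `bin_hi` (percent), `confounded`,
#'   `n_true`, `n_pairs`, `precision` (NA when the subgroup is empty).
#' @export
local_precision_by_confounding <- function(scores, labels, confounded,
                                           rank_bins = default_rank_bins(),
                                           seed = 0L) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels),
            length(scores) == length(confounded))
  m <- length(scores)
  set.seed(seed)
  perm <- sample.int(m)
  o <- perm[order(scores[perm], decreasing = TRUE)]
  pct <- 100 * seq_len(m) / m
  bin <- cut(pct, rank_bins, include.lowest = TRUE)
  lab_o <- labels[o]; conf_o <- as.logical(confounded)[o]
  out <- list()
  for (b in seq_len(length(rank_bins) - 1L)) {
    in_bin <- as.integer(bin) == b
    for (cf in c(FALSE, TRUE)) {
      sel <- in_bin & (conf_o == cf)
      np <- sum(sel)
      out[[length(out) + 1L]] <- data.frame(
        bin_lo = rank_bins[b], bin_hi = rank_bins[b + 1L],
        confounded = cf, n_true = sum(lab_o[sel]), n_pairs = np,
        precision = if (np > 0) sum(lab_o[sel]) / np else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Observed precision at posterior-probability cutoffs
#'
#' For each cutoff c, the precision among predictions with score >= c and
#' their count. On calibrated scores the observed precision tracks the
#' cutoff, supporting the reading of the posteriors as empirical local
#' precision estimates.
#'
#' @inheritParams auroc
#' @param thresholds Score cutoffs (default 0.1, 0.2, ..., 0.9).
#' @return Data frame: `threshold`, `n_predictions`, `precision` (NA when
#'   no prediction clears the cutoff).
#' @export
precision_vs_estimated <- function(scores, labels,
                                   thresholds = seq(0.1, 0.9, by = 0.1)) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  rows <- lapply(thresholds, function(th) {
    sel <- !is.na(scores) & scores >= th
    data.frame(threshold = th, n_predictions = sum(sel),
               precision = if (any(sel)) mean(labels[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' ROC and PR curve coordinates
#'
#' @inheritParams auroc
#' @return List with `roc` (fpr, tpr) and `pr` (recall, precision) data
#'   frames over the achievable points.
#' @export
prediction_curves <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop("curves undefined: both classes must be present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)
  tp <- c(0, cumsum(y)[last]); fp <- c(0, cumsum(!y)[last])
  list(roc = data.frame(fpr = fp / N, tpr = tp / P),
       pr = data.frame(recall = tp / P,
                       precision = ifelse(tp + fp > 0, tp / (tp + fp),
                                          NA_real_)))
}
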