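# Rank-based inverse-normal transformation ("supernormalization") of
# expression rows and validation/encoding of genotype vectors.

#' Supernormalize a numeric vector
#'
#' Maps a vector of expression values onto standard-normal quantiles of its
#' ranks (Blom offset, average ranks for ties) and then rescales exactly to
#' zero mean and unit variance (biased, 1/n convention). The result is a
#' strictly monotone function of the input ranks, so Spearman correlation
#' with the input is 1 (up to ties), while the marginal shape is forced to a
#' standard normal. All downstream likelihood-ratio statistics assume their
#' inputs went through this step (or through [znormalize()]).
#'
#' @param x Numeric vector, length >= 3, no missing values, not all equal.
#' @return Numeric vector of the same length with mean 0 and biased variance
#'   1 (both within 1e-9).
#' @examples
#' supernormalize(c(3.2, 1.1, 5.6, 2.0, 4.4))
#' @export
supernormalize <- function(x) {
  validate_expression_row(x)
  r <- rank(x, ties.method = "average")
  n <- length(x)
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  standardize(z)
}

#' Z-score a numeric vector (biased variance)
#'
#' Shifts and scales to zero mean and unit variance without altering the
#' distribution shape. Used in place of [supernormalize()] inside the
#' measurement-error simulation, and available as a pipeline switch.
#'
#' @param x Numeric vector, length >= 3, no missing values, not all equal.
#' @return Numeric vector with mean 0 and biased variance 1.
#' @export
znormalize <- function(x) {
  validate_expression_row(x)
  standardize(x)
}

# Exact standardization with the 1/n (MLE) variance convention.
standardize <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  x / sqrt(s2)
}

validate_expression_row <- function(x) {
  if (!is.numeric(x)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("expression values contain missing or non-finite entries",
         call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("at least 3 values are required", call. = FALSE)
  }
  if (max(x) - min(x) <= 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  invisible(TRUE)
}

#' Supernormalize every row of an expression matrix
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param method `"supernormalize"` (rank-based inverse normal, default) or
#'   `"znormalize"` (plain shift/scale).
#' @return Matrix of the same shape and dimnames; every row has mean 0 and
#'   biased variance 1.
#' @export
supernormalize_matrix <- function(mat, method = c("supernormalize",
                                                  "znormalize")) {
  method <- match.arg(method)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression input must be a numeric matrix", call. = FALSE)
  }
  f <- if (method == "supernormalize") supernormalize else znormalize
  out <- t(apply(mat, 1L, f))
  dimnames(out) <- dimnames(mat)
  out
}

#' Encode a raw genotype vector
#'
#' Summarizes an integer genotype vector into the bookkeeping the
#' likelihood-ratio tests need: per-category sample counts `n_j`, the number
#' of categories actually present `n_v`, and the implied maximum allele
#' count `n_a`. Categories absent from the sample are excluded from every
#' downstream per-genotype sum.
#'
#' @param raw Vector of non-negative integers (one genotype per sample).
#' @return An object of class `"genotype_vector"`: a list with `values`,
#'   `n`, `n_j` (named integer vector over observed categories), `n_v`,
#'   and `n_a`.
#' @examples
#' g <- encode_genotypes(c(0, 0, 1, 1, 2))
#' g$n_v  # 3
#' @export
encode_genotypes <- function(raw) {
  if (is.factor(raw)) raw <- as.integer(as.character(raw))
  if (!is.numeric(raw)) {
    stop("genotypes must be numeric", call. = FALSE)
  }
  if (anyNA(raw)) {
    stop("genotypes contain missing values", call. = FALSE)
  }
  if (any(raw < 0) || any(raw != round(raw))) {
    stop("genotypes must be non-negative integers", call. = FALSE)
  }
  values <- as.integer(raw)
  tab <- table(values)
  n_j <- as.integer(tab)
  names(n_j) <- names(tab)
  structure(
    list(values = values,
         n = length(values),
         n_j = n_j,
         n_v = length(n_j),
         n_a = max(values)),
    class = "genotype_vector"
  )
}

#' @export
print.genotype_vector <- function(x, ...) {
  cat(sprintf("<genotype_vector> n = %d, n_v = %d, n_a = %d\n",
              x$n, x$n_v, x$n_a))
  print(x$n_j)
  invisible(x)
}

as_genotype_vector <- function(E) {
  if (inherits(E, "genotype_vector")) E else encode_genotypes(E)
}
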