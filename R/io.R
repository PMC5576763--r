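# TSV readers/writers. One exchange dialect everywhere: tab-separated,
# UTF-8, header row; gene/sample IDs restricted to [A-Za-z0-9._:-]+.

.id_regex <- "^[A-Za-z0-9._:-]+$"

check_ids <- function(ids, what, path) {
  bad <- ids[!grepl(.id_regex, ids)]
  if (length(bad)) {
    stop(sprintf("%s: invalid %s ID(s): %s", path, what,
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate %s ID(s): %s", path, what,
                 paste(utils::head(dup, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Shared strict TSV matrix reader: first column row IDs, header row of
# column IDs; every cell must satisfy `cell_ok`, errors carry 1-based
# file line numbers.
read_tsv_matrix <- function(path, what, integer_cells = FALSE,
                            na_ok = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) {
    stop(path, ": need a header row and at least one data row",
         call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (length(samples) < 1L) stop(path, ": no sample columns", call. = FALSE)
  check_ids(samples, "sample", path)
  nfield <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != nfield) {
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 1L,
                   length(f), nfield), call. = FALSE)
    }
    ids[i] <- f[1L]
    cells <- f[-1L]
    v <- suppressWarnings(as.numeric(cells))
    if (na_ok) v[cells == "NA"] <- NA_real_
    if (anyNA(v) && !(na_ok && all(is.na(v) == (cells == "NA")))) {
      stop(sprintf("%s: line %d: non-numeric cell '%s'", path, i + 1L,
                   cells[which(is.na(v) & cells != "NA")[1L]]),
           call. = FALSE)
    }
    if (integer_cells && any(v != round(v) | v < 0)) {
      stop(sprintf(
        "%s: line %d: genotype cells must be non-negative integers",
        path, i + 1L), call. = FALSE)
    }
    vals[i, ] <- v
  }
  check_ids(ids, what, path)
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read an expression matrix from TSV
#'
#' Layout: header row of sample IDs; each following row is one gene, the
#' first column its ID. Ragged rows, non-numeric cells and duplicate IDs
#' are rejected with the offending line number.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) read_tsv_matrix(path, "gene")

#' Read a genotype matrix from TSV
#'
#' Same layout as [read_expression()] but cells must be non-negative
#' integers (allele dosages / category codes).
#'
#' @param path File path.
#' @return Integer-valued numeric matrix, eQTLs x samples.
#' @export
read_genotypes <- function(path) {
  read_tsv_matrix(path, "eQTL", integer_cells = TRUE)
}

#' Read a probability/score matrix from TSV
#'
#' Like [read_expression()] but permits literal `NA` cells (unscored
#' self-pairs), so every matrix written by [write_scores()] is
#' re-readable.
#'
#' @param path File path.
#' @return Numeric matrix, possibly with NA entries.
#' @export
read_score_matrix <- function(path) {
  read_tsv_matrix(path, "gene", na_ok = TRUE)
}

#' Read an (eQTL, gene) pairing from TSV
#'
#' Two named columns `eqtl` and `gene`, one row per anchored pair.
#'
#' @param path File path.
#' @param genotypes,expression Optional matrices to validate IDs against.
#' @return Data frame with columns `eqtl`, `gene`.
#' @export
read_pairs <- function(path, genotypes = NULL, expression = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("eqtl", "gene") %in% names(df))) {
    stop(path, ": header must contain columns 'eqtl' and 'gene'",
         call. = FALSE)
  }
  if (!is.null(genotypes)) {
    bad <- setdiff(df$eqtl, rownames(genotypes))
    if (length(bad)) {
      stop(path, ": unknown eQTL ID(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(expression)) {
    bad <- setdiff(df$gene, rownames(expression))
    if (length(bad)) {
      stop(path, ": unknown gene ID(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  df[, c("eqtl", "gene")]
}

#' Write a matrix in the package's TSV dialect
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the leading ID column.
#' @param digits Decimal places for numeric cells (NULL = full precision).
#' @export
write_tsv_matrix <- function(mat, path, id_col = "id", digits = NULL) {
  vals <- mat
  if (!is.null(digits)) {
    vals <- matrix(formatC(mat, digits = digits, format = "f"),
                   nrow = nrow(mat), dimnames = dimnames(mat))
    vals[is.na(mat)] <- "NA"
  }
  df <- data.frame(rownames(mat), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write all score matrices of a score set
#'
#' One TSV per score (rows = A genes, columns = candidate B genes,
#' probabilities with 6 decimals) plus a long-format table of all scored
#' pairs.
#'
#' @param x A `score_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_scores <- function(x, dir) {
  stopifnot(inherits(x, "score_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("P0", "P2", "P3", "P4", "P5", "PT", "P")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv_matrix(x[[nm]], f, id_col = "gene", digits = 6)
    files <- c(files, f)
  }
  f <- file.path(dir, "scores_long.tsv")
  long <- score_long(x)
  num <- vapply(long, is.numeric, logical(1))
  long[num] <- lapply(long[num], function(v) formatC(v, digits = 6,
                                                     format = "f"))
  utils::write.table(long, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, f))
}

#' Read a key=value configuration file
#'
#' INI-style: one `key = value` per line, `#` comments, blank lines
#' ignored. Used by the command-line interface; explicit flags win over
#' file values.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$",
                                  lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    stop(path, ": unparseable config line: ", lines[bad[1L]],
         call. = FALSE)
  }
  stats::setNames(vapply(kv, `[`, character(1), 3L),
                  vapply(kv, `[`, character(1), 2L))
}
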