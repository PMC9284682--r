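#' Construct and validate a count matrix
#'
#' A `count_matrix` holds raw gene-by-sample expression counts together with
#' unique gene and sample identifiers. Counts must be finite, nonnegative
#' whole numbers. On disk the convention is genes in rows (bioinformatics
#' standard); the statistics modules transpose to samples x features exactly
#' once, at their entry point.
#'
#' @param counts numeric matrix, genes x samples, nonnegative whole numbers.
#' @param gene_ids character vector of unique gene identifiers
#'   (default: `rownames(counts)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (default: `colnames(counts)`).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (matrix with dimnames), `gene_ids` and `sample_ids`.
#' @examples
#' cm <- count_matrix(matrix(0:3, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("count_matrix: gene_ids and sample_ids are required ",
         "(set dimnames or pass them explicitly)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids))
    stop("count_matrix: dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match id lengths (", length(gene_ids), ", ",
         length(sample_ids), ")")
  if (anyDuplicated(gene_ids))
    stop("count_matrix: duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("count_matrix: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("count_matrix: counts must be finite numbers")
  if (any(counts < 0))
    stop("count_matrix: negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("count_matrix: counts must be whole numbers")
  counts <- round(counts)
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Subset a count matrix by sample ids
#'
#' @param x a `count_matrix`.
#' @param sample_ids sample ids to keep, in the order given.
#' @return a `count_matrix` restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(sample_ids, x$sample_ids)
  if (length(missing))
    stop("subset_samples: unknown sample ids: ",
         paste(missing, collapse = ", "))
  count_matrix(x$counts[, sample_ids, drop = FALSE],
               gene_ids = x$gene_ids, sample_ids = sample_ids)
}

#' Construct and validate a sample metadata table
#'
#' The sample table carries, per sample, the biological group, the processing
#' batch and the low-quality probability `p_low` in `[0, 1]` (in the intended
#' workflow `p_low` comes from an upstream quality classifier such as
#' seqQscorer and is supplied as a column). Extra columns are preserved as
#' opaque annotations.
#'
#' @param df data.frame with at least columns `sample_id`, `group`, `batch`
#'   and `p_low`.
#' @param require_plow if `FALSE`, `p_low` may be missing/NA; quality-based
#'   operations will then refuse the table.
#' @return the validated data.frame with class `sample_table` prepended.
#' @export
sample_table <- function(df, require_plow = TRUE) {
  required <- c("sample_id", "group", "batch", "p_low")
  if (!"p_low" %in% names(df) && !require_plow) df$p_low <- NA_real_
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("sample_table: missing required column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$batch <- as.character(df$batch)
  df$p_low <- as.numeric(df$p_low)
  if (anyDuplicated(df$sample_id))
    stop("sample_table: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  has_p <- !is.na(df$p_low)
  if (require_plow && !all(has_p))
    stop("sample_table: p_low contains missing values")
  if (any(df$p_low[has_p] < 0 | df$p_low[has_p] > 1))
    stop("sample_table: p_low must lie in [0, 1]")
  if (length(unique(df$group)) < 2)
    stop("sample_table: need at least 2 distinct groups")
  class(df) <- unique(c("sample_table", class(df)))
  df
}

#' Read a gene x sample count matrix
#'
#' TSV format: first column gene ids, header row of sample ids, tab-separated,
#' UTF-8, "." decimal separator, ids unquoted. MatrixMarket format: a `.mtx`
#' file with sidecar files `genes.tsv` and `samples.tsv` (one id per line) in
#' the same directory, unless sidecar paths are given.
#'
#' @param path path to the counts file.
#' @param format `"tsv"` or `"mtx"`; default guessed from the file extension.
#' @param genes_path,samples_path sidecar id files for mtx input.
#' @return a validated [count_matrix()]; column order as in the file.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_counts: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, check.names = FALSE, quote = "",
                        stringsAsFactors = FALSE),
      error = function(e) stop("read_counts: cannot parse ", path, ": ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("read_counts: ", path,
                           " has no sample columns")
    gene_ids <- as.character(df[[1]])
    sample_ids <- names(df)[-1]  # before subsetting, which mangles dups
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 2,
                         function(z) any(is.na(suppressWarnings(as.numeric(z))))))
      stop("read_counts: non-numeric entries in column(s): ",
           paste(names(bad), collapse = ", "))
    }
    count_matrix(m, gene_ids = gene_ids, sample_ids = sample_ids)
  } else {
    if (is.null(genes_path))
      genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(samples_path))
      samples_path <- file.path(dirname(path), "samples.tsv")
    for (p in c(genes_path, samples_path))
      if (!file.exists(p))
        stop("read_counts: mtx sidecar file not found: ", p)
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    count_matrix(m, gene_ids = gene_ids, sample_ids = sample_ids)
  }
}

#' Write a count matrix
#'
#' @param x a `count_matrix`.
#' @param path output path (`.tsv`, or `.mtx` with sidecars written next to
#'   it).
#' @param format `"tsv"` or `"mtx"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "mtx")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- data.frame(gene = x$gene_ids, x$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(x$sample_ids, file.path(dirname(path), "samples.tsv"))
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with header columns `sample_id`, `group`, `batch`, `p_low`;
#' extra columns are kept as annotations.
#'
#' @param path path to the TSV file.
#' @inheritParams sample_table
#' @return a validated [sample_table()]; row order as in the file.
#' @export
read_sample_table <- function(path, require_plow = TRUE) {
  if (!file.exists(path)) stop("read_sample_table: file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  sample_table(df, require_plow = require_plow)
}

#' Write a sample metadata table
#'
#' @param x a `sample_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a sample table to a count matrix
#'
#' Joining counts and metadata by `sample_id` must be a bijection; anything
#' else is a hard error. Returns the table reordered to the count matrix's
#' column order.
#'
#' @param counts a `count_matrix`.
#' @param table a `sample_table`.
#' @return the reordered `sample_table`.
#' @export
align_samples <- function(counts, table) {
  stopifnot(inherits(counts, "count_matrix"), inherits(table, "sample_table"))
  only_counts <- setdiff(counts$sample_ids, table$sample_id)
  only_table <- setdiff(table$sample_id, counts$sample_ids)
  if (length(only_counts) || length(only_table))
    stop("align_samples: sample ids do not match; only in counts: [",
         paste(only_counts, collapse = ", "), "]; only in table: [",
         paste(only_table, collapse = ", "), "]")
  out <- table[match(counts$sample_ids, table$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: refuse tables whose p_low is unusable for quality operations
require_plow <- function(table, what) {
  if (any(is.na(table$p_low)))
    stop(what, ": p_low has missing values; quality-based operations ",
         "require a complete p_low column")
  invisible(table)
}
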