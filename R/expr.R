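#' Construct an expression matrix
#'
#' Wraps a numeric genes-by-samples matrix together with a declaration of what
#' its cells hold: integer read counts (RNA-seq) or continuous signals
#' (microarray intensities, possibly log-transformed). All downstream
#' functions use the declaration to enforce their preconditions, e.g. the
#' differential expression test requires counts and the log2 floor transform
#' requires continuous signals.
#'
#' Orientation is fixed: rows are genes, columns are samples. There is no
#' auto-transpose and missing values are not supported.
#'
#' @param x numeric matrix, genes in rows and samples in columns, with unique
#'   non-empty rownames (gene ids) and colnames (sample ids). All values must
#'   be finite and non-negative; for `type = "counts"` they must be whole
#'   numbers.
#' @param type `"counts"` or `"continuous"`.
#' @return `x` with class `"expr_mat"` and attribute `value_type`.
#' @examples
#' m <- matrix(rpois(12, 10), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- expr_matrix(m, "counts")
#' expr_type(em)
#' @export
expr_matrix <- function(x, type = c("counts", "continuous")) {
  type <- match.arg(type)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("'x' must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!nzchar(rownames(x))) || any(!nzchar(colnames(x))))
    stop("empty gene or sample id")
  if (anyNA(x) || any(!is.finite(x)))
    stop("missing or non-finite values are not supported")
  if (any(x < 0))
    stop("negative expression values are not allowed")
  if (type == "counts" && any(x != floor(x)))
    stop("type = \"counts\" but matrix contains fractional values")
  structure(x, value_type = type, class = c("expr_mat", class(matrix())))
}

#' @rdname expr_matrix
#' @export
expr_type <- function(x) {
  t <- attr(x, "value_type")
  if (is.null(t)) stop("not an expression matrix (no value_type attribute)")
  t
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), expr_type(x)))
  n <- min(nrow(x), 6L)
  m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... %d more genes\n", nrow(x) - n))
  invisible(x)
}

# re-wrap a plain matrix with the type of a template
.rewrap <- function(x, template) expr_matrix(x, expr_type(template))

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample ids and a first column of gene ids; the body
#' must be numeric and non-negative. Row and column order are preserved as
#' read. Any NA / non-numeric cell is an error, as is a duplicate id.
#'
#' @param path path to a TSV/CSV file.
#' @param type `"counts"` or `"continuous"` (declared, not guessed).
#' @param sep field delimiter, default tab.
#' @return an [expr_matrix()].
#' @seealso [write_expr_matrix()]
#' @export
read_expr_matrix <- function(path, type = c("counts", "continuous"),
                             sep = "\t") {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  # read the header ourselves: read.table would silently uniquify
  # duplicate sample ids, which must instead be an error
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, colClasses = NA,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("expected a gene-id column plus >= 1 sample column")
  sample_ids <- if (length(header) == ncol(df)) header[-1L] else header
  if (length(sample_ids) != ncol(df) - 1L)
    stop("header has ", length(header), " fields for ", ncol(df) - 1L,
         " sample columns")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]]))
      stop("non-numeric or missing cell in column '", sample_ids[j], "'")
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, sample_ids)
  expr_matrix(m, type)
}

#' Write an expression matrix to a delimited text file
#'
#' Writes a header row of sample ids and a first `gene_id` column, so that
#' [read_expr_matrix()] recovers the matrix cell-for-cell.
#'
#' @param x an [expr_matrix()].
#' @param path output path.
#' @param sep field delimiter, default tab.
#' @export
write_expr_matrix <- function(x, path, sep = "\t") {
  expr_type(x)  # validates
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels
#'
#' Reads a two-column table (sample id, group id). Returns a factor named by
#' sample id whose levels are ordered by first appearance in the file, which
#' fixes the deterministic group order used in all reports.
#'
#' @param path path to a two-column TSV (no header by default).
#' @param header logical; does the file carry a header row?
#' @param sep field delimiter, default tab.
#' @return named factor: `names()` are sample ids, values are group ids.
#' @export
read_group_labels <- function(path, header = FALSE, sep = "\t") {
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("expected exactly 2 columns (sample_id, group_id)")
  group_labels(stats::setNames(df[[2L]], df[[1L]]))
}

#' Construct group labels from a named vector
#'
#' @param x named character vector or named factor mapping sample id to
#'   group id. Group level order is order of first appearance.
#' @return named factor.
#' @export
group_labels <- function(x) {
  if (is.factor(x)) x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("group labels must be named by sample id")
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    stop("duplicated sample id(s) in labels: ", paste(dup, collapse = ", "))
  }
  if (anyNA(x) || any(!nzchar(x))) stop("empty group id")
  factor(x, levels = unique(x))
}

# Align labels to the matrix columns; every sample must be labelled.
.match_groups <- function(x, groups) {
  groups <- group_labels(groups)
  missing <- setdiff(colnames(x), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  g <- groups[colnames(x)]
  droplevels(g)
}
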