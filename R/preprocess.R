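#' Drop genes with zero expression in every sample
#'
#' The first of the two gene filters applied before any distance or DE
#' computation: a gene is kept iff at least one sample has a non-zero value.
#' Gene order is preserved; retained values are untouched.
#'
#' @param x an [expr_matrix()].
#' @return list with `matrix` (filtered [expr_matrix()]) and `report`
#'   (a [filter_report()]).
#' @export
filter_zero <- function(x) {
  expr_type(x)
  keep <- rowSums(unclass(x) != 0) > 0L
  if (!any(keep)) stop("all genes have zero expression in every sample")
  out <- .rewrap(unclass(x)[keep, , drop = FALSE], x)
  list(matrix = out,
       report = filter_report(n_input = nrow(x), n_after_zero = nrow(out)))
}

#' Collapse genes with identical expression patterns
#'
#' The second filter, applied before distance computation only: genes whose
#' full row vectors are exactly equal (no tolerance) are collapsed to a single
#' representative, the first occurrence in gene order. Rank-based sample
#' distances are unaffected by which representative survives; the collapse
#' reduces the weight of low/flat expression patterns (in count data, mostly
#' all-zero-after-subsampling and other low-count ties).
#'
#' @param x an [expr_matrix()].
#' @return list with `matrix` and `report` as in [filter_zero()]; the report
#'   additionally carries `collapsed_group_sizes`, the multiset of duplicate
#'   class sizes.
#' @export
filter_unique <- function(x) {
  expr_type(x)
  key <- apply(unclass(x), 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  out <- .rewrap(unclass(x)[first, , drop = FALSE], x)
  list(matrix = out,
       report = filter_report(n_input = nrow(x), n_after_unique = nrow(out),
                              collapsed_group_sizes =
                                as.integer(table(match(key, key[first])))))
}

#' Filter report
#'
#' Bookkeeping record for the gene filters: how many genes entered, how many
#' survived the all-zero filter and the unique-pattern collapse.
#'
#' @param n_input genes in.
#' @param n_after_zero genes after the all-zero filter (NA if not run).
#' @param n_after_unique genes after the unique-pattern collapse (NA if not
#'   run).
#' @param collapsed_group_sizes integer vector of duplicate class sizes.
#' @return object of class `"filter_report"`.
#' @export
filter_report <- function(n_input, n_after_zero = NA_integer_,
                          n_after_unique = NA_integer_,
                          collapsed_group_sizes = integer()) {
  structure(list(n_input = as.integer(n_input),
                 n_after_zero = as.integer(n_after_zero),
                 n_after_unique = as.integer(n_after_unique),
                 collapsed_group_sizes = collapsed_group_sizes),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Gene filtering:", x$n_input, "genes in")
  if (!is.na(x$n_after_zero)) cat(" ->", x$n_after_zero, "after zero filter")
  if (!is.na(x$n_after_unique))
    cat(" ->", x$n_after_unique, "after unique filter")
  cat("\n")
  invisible(x)
}

#' Apply the standard filter pipeline
#'
#' Runs the all-zero filter and (optionally) the unique-pattern collapse in
#' that order, merging the two reports. DE analysis conventionally uses the
#' zero-filtered matrix; distances / silhouettes / clustering use the
#' zero-then-unique-filtered matrix.
#'
#' @param x an [expr_matrix()].
#' @param unique_filter collapse identical rows after the zero filter?
#' @return list with `matrix` and `report`.
#' @export
filter_genes <- function(x, unique_filter = TRUE) {
  z <- filter_zero(x)
  if (!unique_filter)
    return(list(matrix = z$matrix,
                report = filter_report(n_input = nrow(x),
                                       n_after_zero = nrow(z$matrix))))
  u <- filter_unique(z$matrix)
  list(matrix = u$matrix,
       report = filter_report(n_input = nrow(x),
                              n_after_zero = nrow(z$matrix),
                              n_after_unique = nrow(u$matrix),
                              collapsed_group_sizes =
                                u$report$collapsed_group_sizes))
}

#' Floor microarray signals at 1 and log2-transform
#'
#' The conventional microarray preprocessing step: signals below 1 are set to
#' 1 and all values are then log2-transformed, so the result is non-negative.
#' Refuses count matrices — counts go to the NB test untransformed.
#'
#' @param x an [expr_matrix()] with `type = "continuous"`.
#' @return transformed [expr_matrix()], still continuous.
#' @export
log2_floor <- function(x) {
  if (expr_type(x) != "continuous")
    stop("log2_floor() applies to continuous (microarray) signals, not counts")
  .rewrap(log2(pmax(unclass(x), 1)), x)
}
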