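#' Hierarchical sample clustering (average linkage)
#'
#' Agglomerative clustering of samples with unweighted average linkage
#' (UPGMA): the distance between two clusters is the mean over all cross-pair
#' sample distances. Run on the 1 - Spearman distance this reproduces the
#' standard sample dendrogram shown next to average-silhouette reports.
#'
#' @param d a `stats::dist` over >= 2 samples, all distances finite.
#' @return an object of class `hclust` (see [stats::hclust()]); merge heights
#'   are non-decreasing because average linkage is monotone.
#' @seealso [write_newick()] to serialize the tree.
#' @export
cluster_samples <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("need >= 2 samples to cluster")
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances")
  stats::hclust(d, method = "average")
}

#' Write a sample dendrogram as Newick
#'
#' Serializes an `hclust` tree to a Newick string with leaf names equal to the
#' sample ids and the midpoint branch-length convention: node heights are half
#' the merge heights, so the leaf-to-leaf path length in the tree equals the
#' cophenetic distance of the clustering. Leaf names containing Newick
#' metacharacters are quoted. The file ends with ";".
#'
#' @param tree an `hclust` object with >= 2 leaves.
#' @param path output file path.
#' @return the Newick string, invisibly.
#' @examples
#' dm <- matrix(c(0, .4, .4, 0), 2, 2,
#'              dimnames = list(c("A1", "B1"), c("A1", "B1")))
#' f <- tempfile(fileext = ".nwk")
#' write_newick(cluster_samples(as.dist(dm)), f)
#' readLines(f)  # "(A1:0.2,B1:0.2);"
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "hclust")) stop("'tree' must be an hclust object")
  if (length(tree$labels) < 2L) stop("cannot serialize a tree with < 2 leaves")
  lab <- tree$labels
  meta <- grepl("[](),:;'[ \t]", lab)
  lab[meta] <- paste0("'", gsub("'", "''", lab[meta], fixed = TRUE), "'")
  # node heights halved so leaf-to-leaf path length = cophenetic distance
  node <- function(i, parent_h) {
    if (i < 0) {                       # negative merge entries are leaves
      h <- 0
      body <- lab[-i]
    } else {
      h <- tree$height[i]
      body <- paste0("(", node(tree$merge[i, 1], h), ",",
                     node(tree$merge[i, 2], h), ")")
    }
    paste0(body, ":", format((parent_h - h) / 2, digits = 10))
  }
  root <- nrow(tree$merge)
  s <- paste0("(", node(tree$merge[root, 1], tree$height[root]), ",",
              node(tree$merge[root, 2], tree$height[root]), ");")
  writeLines(s, path)
  invisible(s)
}
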