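#' Spearman correlation distance between samples
#'
#' Computes the pairwise sample distance d = 1 - rho, where rho is Spearman's
#' rank correlation (average ranks for ties) between two sample columns over
#' all genes of the supplied (already filtered) matrix. The distance lies in
#' [0, 2] and is invariant under any monotone transform of each sample's
#' values, which is what makes it robust for raw counts.
#'
#' @param x an [expr_matrix()] (or plain numeric matrix, genes x samples)
#'   with >= 2 samples and >= 2 genes.
#' @return a `stats::dist` object over samples, attribute `method =
#'   "spearman"`.
#' @examples
#' m <- matrix(rpois(300, 20), 50, 6,
#'             dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
#' d <- spearman_dist(expr_matrix(m, "counts"))
#' range(d)
#' @export
spearman_dist <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m) || !is.numeric(m)) stop("'x' must be a numeric matrix")
  if (ncol(m) < 2L) stop("need >= 2 samples")
  if (nrow(m) < 2L) stop("need >= 2 genes")
  constant <- apply(m, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant))
    stop("sample(s) with constant expression across all genes ",
         "(Spearman correlation undefined): ",
         paste(colnames(m)[constant], collapse = ", "))
  rho <- stats::cor(m, method = "spearman")
  d <- stats::as.dist(1 - rho)
  attr(d, "method") <- "spearman"
  d
}

#' Intra- and inter-group mean distances
#'
#' Summarizes a sample distance matrix per group: the mean pairwise distance
#' within each group and the mean distance between each pair of groups. Small
#' intra-group means indicate tight groups; a ratio of intra to inter means
#' near 1 indicates intermingled groups and anticipates a near-zero average
#' silhouette.
#'
#' @param d a `stats::dist` over samples (e.g. from [spearman_dist()]).
#' @param groups sample group labels (see [group_labels()]); every sample in
#'   `d` must be labelled.
#' @return list with `intra` (named numeric; NA for singleton groups) and
#'   `inter` (data.frame: group_a, group_b, mean_distance).
#' @export
group_distance_summary <- function(d, groups) {
  dm <- as.matrix(d)
  g <- .match_groups(dm, groups)
  lev <- levels(g)
  intra <- vapply(lev, function(gr) {
    i <- which(g == gr)
    if (length(i) < 2L) return(NA_real_)
    mean(dm[i, i][upper.tri(dm[i, i])])
  }, numeric(1))
  pairs <- utils::combn(lev, 2L)
  inter <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    mean_distance = apply(pairs, 2L, function(p)
      mean(dm[g == p[1L], g == p[2L], drop = FALSE])),
    stringsAsFactors = FALSE)
  list(intra = intra, inter = inter)
}
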