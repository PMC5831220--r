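#' Silhouette scores for predefined sample groups
#'
#' Computes per-sample silhouette indices against *predefined* groups rather
#' than discovered clusters. For sample i with group g(i):
#' \deqn{u_i = \mathrm{mean}\,d(i, j),\ j \in g(i),\ j \ne i}
#' \deqn{v_i = \min_{h \ne g(i)} \mathrm{mean}\,d(i, j),\ j \in h}
#' \deqn{s_i = (v_i - u_i) / \max(u_i, v_i)}
#' so s_i is positive when sample i sits closer to its own group than to the
#' nearest other group, negative when the reverse holds, and zero when
#' indifferent. The average silhouette AS is the mean of s_i over all samples
#' and summarizes the degree of separation of the grouping on a -1..1 scale.
#'
#' With exactly two groups v_i is simply the mean distance from i to the other
#' group; with more groups the standard nearest-other-group minimum is used.
#' Two edge cases are defined by convention: a sample alone in its group gets
#' s_i = 0, and s_i = 0 whenever max(u_i, v_i) = 0 (all relevant distances
#' zero — an indifferent sample).
#'
#' @param d a `stats::dist` over samples, e.g. from [spearman_dist()].
#' @param groups group labels for the samples in `d` (see [group_labels()]);
#'   at least 2 distinct groups are required.
#' @return object of class `"group_silhouette"`: a list with
#'   \describe{
#'     \item{samples}{data.frame with columns sample, group, u, v, s}
#'     \item{AS}{mean of s over all samples}
#'     \item{group_means}{named numeric, mean s per group}
#'   }
#' @references Rousseeuw, P. J. (1987) Silhouettes: a graphical aid to the
#'   interpretation and validation of cluster analysis. J. Comput. Appl.
#'   Math. 20, 53-65.
#' @examples
#' dm <- matrix(0.9, 4, 4); dm[1, 2] <- dm[2, 1] <- 0.1
#' dm[3, 4] <- dm[4, 3] <- 0.1; diag(dm) <- 0
#' dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
#' g <- group_labels(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' group_silhouette(as.dist(dm), g)
#' @export
group_silhouette <- function(d, groups) {
  dm <- as.matrix(d)
  if (is.null(rownames(dm))) stop("'d' must carry sample names")
  g <- .match_groups(dm, groups)
  if (nlevels(g) < 2L)
    stop("need >= 2 distinct groups for silhouette computation")
  n <- nrow(dm)
  u <- v <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(g == g[i]); own <- own[own != i]
    if (!length(own)) {            # singleton group: indifferent by convention
      u[i] <- v[i] <- s[i] <- 0
      next
    }
    u[i] <- mean(dm[i, own])
    other_means <- vapply(setdiff(levels(g), as.character(g[i])),
                          function(h) mean(dm[i, g == h]), numeric(1))
    v[i] <- min(other_means)
    mx <- max(u[i], v[i])
    s[i] <- if (mx == 0) 0 else (v[i] - u[i]) / mx
  }
  samples <- data.frame(sample = rownames(dm), group = g, u = u, v = v, s = s,
                        stringsAsFactors = FALSE)
  structure(list(samples = samples,
                 AS = mean(s),
                 group_means = vapply(levels(g), function(h)
                   mean(s[g == h]), numeric(1))),
            class = "group_silhouette")
}

#' @export
print.group_silhouette <- function(x, digits = 4, ...) {
  cat(sprintf("Group silhouette over %d samples in %d groups\n",
              nrow(x$samples), length(x$group_means)))
  cat("  AS =", format(x$AS, digits = digits), "\n")
  gm <- format(x$group_means, digits = digits)
  cat("  group means:",
      paste(names(x$group_means), gm, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.group_silhouette <- function(object, ...) {
  cat(sprintf("Group silhouette: AS = %.4f (%d samples, %d groups)\n\n",
              object$AS, nrow(object$samples), length(object$group_means)))
  print(object$samples, row.names = FALSE)
  invisible(object)
}

#' Score a grouping on an expression matrix
#'
#' One-stop wrapper for the full average-silhouette pipeline: filter genes
#' (all-zero filter, then optionally the unique-pattern collapse), compute the
#' 1 - Spearman sample distance on the filtered matrix, and evaluate the
#' silhouette of the supplied grouping. For continuous (microarray) matrices
#' an optional floor-at-1 log2 transform is applied first.
#'
#' @param x an [expr_matrix()].
#' @param groups group labels (see [group_labels()]).
#' @param unique_filter collapse identical expression patterns before the
#'   distance computation? Default TRUE.
#' @param log2_transform for continuous matrices, apply [log2_floor()] first.
#' @return a [group_silhouette()] object, augmented with `n_genes_used`,
#'   `filter_report`, and the `dist` used.
#' @examples
#' sim <- simulate_counts(n_genes = 300, p_deg = 0.3, n_rep_a = 4,
#'                        n_rep_b = 4, seed = 1)
#' score_groups(sim$counts, sim$groups)
#' @export
score_groups <- function(x, groups, unique_filter = TRUE,
                         log2_transform = FALSE) {
  if (log2_transform) x <- log2_floor(x)
  f <- filter_genes(x, unique_filter = unique_filter)
  d <- spearman_dist(f$matrix)
  res <- group_silhouette(d, groups)
  res$n_genes_used <- nrow(f$matrix)
  res$filter_report <- f$report
  res$dist <- d
  res
}
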