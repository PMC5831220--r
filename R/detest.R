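#' Per-sample normalization factors for count data
#'
#' Returns one positive factor per sample, interpreted as the sample's
#' relative effective sequencing depth: dividing a sample's counts by its
#' factor puts all samples on a common scale. Factors are rescaled to
#' geometric mean 1.
#'
#' Methods:
#' \describe{
#'   \item{`"libsize"`}{proportional to the column (library) sums.}
#'   \item{`"tmm"`}{library sum times the trimmed-mean-of-M-values
#'     scaling factor (edgeR's TMM), robust to a minority of DEGs.}
#'   \item{`"degespipe"`}{iterative DEG-elimination: for 3 rounds, normalize
#'     (TMM), run the exact NB test, drop genes with q <= 0.1, and recompute
#'     TMM on the remaining (putatively non-DE) genes. The final factors are
#'     returned for the full matrix.}
#' }
#'
#' @param x an [expr_matrix()] with `type = "counts"`, no all-zero columns.
#' @param groups group labels; required by `"degespipe"`, ignored otherwise.
#' @param method `"tmm"` (default), `"libsize"` or `"degespipe"`.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
norm_factors <- function(x, groups = NULL,
                         method = c("tmm", "libsize", "degespipe")) {
  method <- match.arg(method)
  if (expr_type(x) != "counts") stop("normalization factors require counts")
  m <- unclass(x)
  libs <- colSums(m)
  if (any(libs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m)[libs == 0], collapse = ", "))
  f <- switch(method,
    libsize = libs,
    tmm = libs * edgeR::calcNormFactors(m, method = "TMM"),
    degespipe = {
      if (is.null(groups)) stop("method \"degespipe\" requires group labels")
      g <- .match_groups(x, groups)
      cur <- x
      fac <- norm_factors(x, method = "tmm")
      for (iter in 1:3) {
        de <- nb_exact_test(cur, g, factors = fac[colnames(cur)])
        keep <- de$table$q > 0.1
        if (!any(keep)) break
        cur <- .rewrap(unclass(cur)[keep, , drop = FALSE], cur)
        fac <- norm_factors(cur, method = "tmm")
      }
      # depth estimated on non-DE genes, applied to the full matrix
      fac
    })
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

# Exact p-value for an NB split: given total t = yA + yB of group-sum counts
# with per-group sums Y_A ~ NB(nA mu, size nA/phi), Y_B ~ NB(nB mu, size
# nB/phi), the two-sided p is the null probability of all splits (k, t - k)
# no more likely than the observed one. phi = 0 is the Poisson limit, where
# the split distribution is Binomial(t, nA/(nA+nB)).
.nb_split_p <- function(y_a, y_b, n_a, n_b, phi) {
  t <- y_a + y_b
  if (t == 0) return(NA_real_)
  k <- 0:t
  if (phi == 0) {
    lp <- stats::dbinom(k, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- t / (n_a + n_b)
    lp <- stats::dnbinom(k, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(t - k, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[y_a + 1] * (1 + 1e-8)])
}

# Method-of-moments dispersion from pseudo-counts (equalized depth), pooled
# within groups so true DE does not inflate phi, then shrunk halfway toward
# the 10%-trimmed mean across genes to stabilize small replicate numbers.
.dispersions <- function(pseudo, g, shrink = 0.5) {
  lev <- levels(g)
  n <- ncol(pseudo)
  ssq <- 0
  for (h in lev) {
    cols <- pseudo[, g == h, drop = FALSE]
    ssq <- ssq + rowSums((cols - rowMeans(cols))^2)
  }
  s2 <- ssq / (n - length(lev))          # pooled within-group variance
  m <- rowMeans(pseudo)
  phi <- pmax((s2 - m) / m^2, 0)
  phi[!is.finite(phi)] <- 0
  common <- mean(phi, trim = 0.1)
  (1 - shrink) * phi + shrink * common
}

#' Exact negative-binomial two-group differential expression test
#'
#' A self-contained DE engine for two-group count comparisons. Per gene it
#' tests equality of group means under an NB model with variance
#' V = mu + phi mu^2:
#' \enumerate{
#'   \item counts are scaled to a common effective library size using the
#'     normalization factors (pseudo-counts);
#'   \item a per-gene dispersion is estimated by pooled within-group method
#'     of moments on the pseudo-counts, floored at 0 and shrunk 50/50 toward
#'     the 10%-trimmed mean dispersion across genes;
#'   \item group pseudo-count totals (y_A, y_B) are formed (rounded to
#'     integers) and the exact two-sided p-value is the null probability of
#'     all splits of y_A + y_B at most as likely as the observed one, under
#'     the NB split distribution (binomial in the Poisson limit phi = 0);
#'   \item p-values are Benjamini-Hochberg adjusted to q-values and genes are
#'     ranked by ascending p.
#' }
#' P_DEG is the percentage of tested genes with q at or below the FDR
#' threshold, and P_trueDEG = P_DEG x (1 - threshold) its statistically
#' expected true-positive share. When per-gene truth is supplied (simulated
#' data) the Mann-Whitney AUC of the p-value ranking is also reported.
#'
#' Genes with zero totals in both groups are excluded with a warning (they
#' should have been removed by [filter_zero()]).
#'
#' @param x an [expr_matrix()] of counts.
#' @param groups labels defining exactly two groups, each with >= 2 samples.
#' @param norm normalization method passed to [norm_factors()] when
#'   `factors` is NULL.
#' @param factors optional precomputed per-sample factors (relative depths).
#' @param fdr FDR threshold for the P_DEG call (default 0.10).
#' @param truth optional logical vector (or the `truth` data.frame of a
#'   `sim_counts` object) flagging true DEGs, for AUC computation.
#' @return object of class `"nb_de"`: list with `table` (data.frame:
#'   gene_id, p, q, rank), `norm_factors`, `dispersion` (per-gene, after
#'   shrinkage), `fdr`, `p_deg` (percent), `p_true_deg` (percent), and `auc`
#'   (NA without truth).
#' @examples
#' sim <- simulate_counts(n_genes = 500, p_deg = 0.2, n_rep_a = 5,
#'                        n_rep_b = 5, seed = 7)
#' de <- nb_exact_test(filter_zero(sim$counts)$matrix, sim$groups,
#'                     truth = sim$truth)
#' de
#' @export
nb_exact_test <- function(x, groups, norm = c("tmm", "libsize", "degespipe"),
                          factors = NULL, fdr = 0.1, truth = NULL) {
  if (expr_type(x) != "counts") stop("the exact NB test requires counts")
  if (fdr < 0 || fdr > 1) stop("'fdr' must lie in [0, 1]")
  g <- .match_groups(x, groups)
  if (nlevels(g) != 2L)
    stop("exactly 2 groups required, got ", nlevels(g))
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples")
  if (is.null(factors)) factors <- norm_factors(x, g, method = match.arg(norm))
  if (length(factors) != ncol(x) || any(factors <= 0))
    stop("'factors' must be ", ncol(x), " positive values")
  if (!is.null(names(factors))) factors <- factors[colnames(x)]

  m <- unclass(x)
  pseudo <- sweep(m, 2L, factors, "/")
  keep <- rowSums(pseudo) > 0
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with zero counts in all samples excluded")
    m <- m[keep, , drop = FALSE]
    pseudo <- pseudo[keep, , drop = FALSE]
  }
  if (!is.null(truth)) {
    if (is.data.frame(truth)) {
      t_flags <- truth$is_deg
      names(t_flags) <- truth$gene_id
      truth <- t_flags
    }
    if (!is.null(names(truth))) truth <- truth[rownames(m)]
    truth <- as.logical(truth)
    if (anyNA(truth)) stop("'truth' must cover every tested gene")
  }

  phi <- .dispersions(pseudo, g)
  a <- g == levels(g)[1L]
  y_a <- round(rowSums(pseudo[, a, drop = FALSE]))
  y_b <- round(rowSums(pseudo[, !a, drop = FALSE]))
  n_a <- sum(a); n_b <- sum(!a)
  p <- vapply(seq_len(nrow(m)), function(i)
    .nb_split_p(y_a[i], y_b[i], n_a, n_b, phi[i]), numeric(1))
  p <- pmin(p, 1)
  q <- stats::p.adjust(p, method = "BH")

  res <- structure(list(
    table = data.frame(gene_id = rownames(m), p = p, q = q,
                       rank = rank(p, ties.method = "first"),
                       stringsAsFactors = FALSE),
    norm_factors = stats::setNames(factors, colnames(m)),
    dispersion = stats::setNames(phi, rownames(m)),
    groups = g,
    fdr = fdr,
    p_deg = 100 * mean(q <= fdr),
    auc = if (is.null(truth)) NA_real_ else auc_vs_truth(p, truth)),
    class = "nb_de")
  res$p_true_deg <- p_true_deg(res$p_deg, fdr)
  res
}

#' @export
print.nb_de <- function(x, ...) {
  cat(sprintf("Exact NB two-group DE test: %d genes (%s vs %s)\n",
              nrow(x$table), levels(x$groups)[1], levels(x$groups)[2]))
  cat(sprintf("  P_DEG = %.2f%% at %.0f%% FDR (P_trueDEG = %.2f%%)\n",
              x$p_deg, 100 * x$fdr, x$p_true_deg))
  if (!is.na(x$auc)) cat(sprintf("  AUC vs truth = %.4f\n", x$auc))
  invisible(x)
}

#' @export
summary.nb_de <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop genes by p-value:\n")
  tab <- object$table[order(object$table$rank), ]
  print(utils::head(tab, n), row.names = FALSE)
  invisible(object)
}

#' Percentage of declared DEGs at an FDR threshold
#'
#' @param de an `"nb_de"` result.
#' @param fdr FDR threshold in [0, 1].
#' @return percentage (0-100 scale) of tested genes with q <= `fdr`.
#' @export
p_deg <- function(de, fdr = de$fdr) {
  if (fdr < 0 || fdr > 1) stop("'fdr' must lie in [0, 1]")
  100 * mean(de$table$q <= fdr)
}

#' Statistically expected true-DEG percentage
#'
#' By the definition of the FDR, of the genes declared at threshold f only a
#' fraction (1 - f) are expected to be true positives, so
#' P_trueDEG = P_DEG x (1 - f). E.g. P_DEG = 0.78% at a 40% FDR gives
#' 0.78 x 0.6 = 0.47% expected true DEGs.
#'
#' @param p_deg declared-DEG percentage (0-100 scale).
#' @param fdr FDR threshold in [0, 1].
#' @return percentage on the 0-100 scale.
#' @export
p_true_deg <- function(p_deg, fdr) {
  if (fdr < 0 || fdr > 1) stop("'fdr' must lie in [0, 1]")
  if (p_deg < 0 || p_deg > 100) stop("'p_deg' is a percentage in [0, 100]")
  p_deg * (1 - fdr)
}

#' AUC of a p-value ranking against known truth
#'
#' Mann-Whitney AUC: the probability that a randomly chosen true DEG has a
#' smaller p-value than a randomly chosen non-DEG, ties counted 1/2.
#' Equals the area under the ROC curve of the ascending-p gene ranking.
#'
#' @param p per-gene p-values (any scores where smaller = more DE).
#' @param is_deg logical vector of the same length; must contain at least one
#'   TRUE and one FALSE.
#' @return AUC in [0, 1].
#' @export
auc_vs_truth <- function(p, is_deg) {
  is_deg <- as.logical(is_deg)
  if (length(p) != length(is_deg)) stop("length mismatch")
  if (!any(is_deg) || all(is_deg))
    stop("need at least one DEG and one non-DEG")
  r <- rank(p)  # midranks
  n1 <- sum(is_deg); n0 <- sum(!is_deg)
  (sum(r[!is_deg]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}
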