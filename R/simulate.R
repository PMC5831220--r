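#' Draw per-gene negative-binomial parameters
#'
#' Produces per-gene (mu, phi) pairs for the count simulator under the
#' variance model V = mu + phi * mu^2. Two sources are supported:
#' \describe{
#'   \item{`"synthetic"`}{log10(mu) ~ Normal(1.0, 0.7) truncated so that
#'     mu lies in [0.5, 1e5] (median mean of 10 reads with a heavy right
#'     tail, the shape typical of bulk RNA-seq count distributions), and
#'     phi ~ Gamma(shape 2, mean 0.15) truncated to [0.001, 2.0]
#'     (moderate overdispersion, biological-replicate scale). Truncation is
#'     by rejection resampling, not clamping.}
#'   \item{`"table"`}{a two-column (mu, phi) table — e.g. moments estimated
#'     from a real dataset — whose rows are resampled with replacement.}
#' }
#'
#' @param n_genes number of genes.
#' @param source `"synthetic"` or `"table"`.
#' @param table for `source = "table"`: a data.frame/matrix with columns
#'   (mu, phi), or a path to a headerless two-column TSV.
#' @param seed optional integer seed for reproducible draws.
#' @return data.frame with columns `mu` (> 0) and `phi` (>= 0), `n_genes`
#'   rows.
#' @export
sim_nb_params <- function(n_genes, source = c("synthetic", "table"),
                          table = NULL, seed = NULL) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  if (source == "synthetic") {
    rtrunc <- function(n, r, lo, hi) {
      x <- r(n)
      bad <- which(x < lo | x > hi)
      while (length(bad)) {
        x[bad] <- r(length(bad))
        bad <- bad[x[bad] < lo | x[bad] > hi]
      }
      x
    }
    mu <- 10^rtrunc(n_genes, function(n) stats::rnorm(n, 1.0, 0.7),
                    log10(0.5), 5)
    phi <- rtrunc(n_genes, function(n) stats::rgamma(n, shape = 2,
                                                     scale = 0.15 / 2),
                  0.001, 2.0)
  } else {
    if (is.null(table)) stop("source = \"table\" requires 'table'")
    if (is.character(table))
      table <- utils::read.table(table, header = FALSE, sep = "\t",
                                 col.names = c("mu", "phi"))
    tab <- as.data.frame(table)
    if (ncol(tab) < 2L) stop("parameter table must have columns (mu, phi)")
    mu <- as.numeric(tab[[1L]]); phi <- as.numeric(tab[[2L]])
    if (anyNA(mu) || anyNA(phi) || any(mu <= 0) || any(phi < 0))
      stop("malformed parameter table: need mu > 0 and phi >= 0")
    i <- sample.int(length(mu), n_genes, replace = TRUE)
    mu <- mu[i]; phi <- phi[i]
  }
  data.frame(mu = mu, phi = phi)
}

# NB draw under V = mu + phi mu^2; phi = 0 degenerates to Poisson
.rnb <- function(n, mu, phi) {
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

#' Simulate a two-group RNA-seq count matrix with known DEGs
#'
#' Generates counts for a two-group comparison (groups "A" and "B") from
#' independent negative-binomial draws with per-gene (mu, phi) from
#' [sim_nb_params()]. A fraction `p_deg` of genes are flagged as true DEGs;
#' each DEG is up-regulated in one group by multiplying that group's mean by
#' `fold_change`, with a fraction `frac_up_a` of the DEGs up in group A.
#' Non-DEGs share the same mean in both groups. Library depths are equal by
#' construction unless a per-sample `depth` multiplier vector is given.
#'
#' Gene counts are exact: `round(n_genes * p_deg)` DEG flags, of which
#' `round(. * frac_up_a)` are up in A. Sample ids are A1..A{n_rep_a},
#' B1..B{n_rep_b}. The same seed reproduces the dataset bit for bit.
#'
#' @param n_genes total number of genes.
#' @param p_deg fraction of genes that are true DEGs, in [0, 1].
#' @param fold_change multiplicative effect on the up-regulated group's mean
#'   (default 4).
#' @param frac_up_a fraction of DEGs up-regulated in group A (default 0.5).
#' @param n_rep_a,n_rep_b replicates per group.
#' @param params optional data.frame (mu, phi) of length `n_genes`; drawn via
#'   [sim_nb_params()] (synthetic source) when NULL.
#' @param depth optional positive per-sample depth multipliers, length
#'   `n_rep_a + n_rep_b`.
#' @param seed optional integer seed.
#' @return object of class `"sim_counts"`: list with
#'   \describe{
#'     \item{counts}{[expr_matrix()] of counts, `n_genes` x
#'       (`n_rep_a` + `n_rep_b`)}
#'     \item{groups}{group labels (named factor, levels A, B)}
#'     \item{truth}{data.frame: gene_id, is_deg, up_group ("A"/"B"/"none")}
#'     \item{params}{the (mu, phi) table used}
#'     \item{config}{the simulation parameters}
#'   }
#' @examples
#' sim <- simulate_counts(n_genes = 1000, p_deg = 0.2, n_rep_a = 3,
#'                        n_rep_b = 3, seed = 42)
#' sum(sim$truth$is_deg)  # exactly 200
#' @export
simulate_counts <- function(n_genes, p_deg, fold_change = 4,
                            frac_up_a = 0.5, n_rep_a, n_rep_b,
                            params = NULL, depth = NULL, seed = NULL) {
  if (p_deg < 0 || p_deg > 1) stop("'p_deg' must lie in [0, 1]")
  if (frac_up_a < 0 || frac_up_a > 1) stop("'frac_up_a' must lie in [0, 1]")
  if (fold_change <= 0) stop("'fold_change' must be positive")
  if (n_rep_a < 1L || n_rep_b < 1L) stop("need >= 1 replicate per group")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- sim_nb_params(n_genes)
  if (nrow(params) != n_genes) stop("'params' must have n_genes rows")

  n_deg <- round(n_genes * p_deg)
  n_up_a <- round(n_deg * frac_up_a)
  up_group <- rep("none", n_genes)
  if (n_deg > 0L) {
    up_group[seq_len(n_deg)] <- c(rep("A", n_up_a), rep("B", n_deg - n_up_a))
    # shuffle DEG positions so truth is not ordered by gene index
    up_group <- up_group[sample.int(n_genes)]
  }
  mu_a <- ifelse(up_group == "A", params$mu * fold_change, params$mu)
  mu_b <- ifelse(up_group == "B", params$mu * fold_change, params$mu)

  n_samp <- n_rep_a + n_rep_b
  if (is.null(depth)) depth <- rep(1, n_samp)
  if (length(depth) != n_samp || any(depth <= 0))
    stop("'depth' must be ", n_samp, " positive multipliers")

  counts <- matrix(0, n_genes, n_samp)
  for (j in seq_len(n_samp)) {
    mu_j <- if (j <= n_rep_a) mu_a else mu_b
    counts[, j] <- .rnb(n_genes, mu_j * depth[j], params$phi)
  }
  dimnames(counts) <- list(paste0("g", seq_len(n_genes)),
                           c(paste0("A", seq_len(n_rep_a)),
                             paste0("B", seq_len(n_rep_b))))
  groups <- group_labels(stats::setNames(
    rep(c("A", "B"), c(n_rep_a, n_rep_b)), colnames(counts)))
  structure(list(
    counts = expr_matrix(counts, "counts"),
    groups = groups,
    truth = data.frame(gene_id = rownames(counts),
                       is_deg = up_group != "none",
                       up_group = up_group, stringsAsFactors = FALSE),
    params = params,
    config = list(n_genes = n_genes, p_deg = p_deg,
                  fold_change = fold_change, frac_up_a = frac_up_a,
                  n_rep_a = n_rep_a, n_rep_b = n_rep_b, seed = seed)),
    class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Simulated two-group count data: %d genes x (%d + %d) ",
                     "samples\n  %d true DEGs (%.1f%%), fold change %g, ",
                     "%d up in A\n"),
              cfg$n_genes, cfg$n_rep_a, cfg$n_rep_b, sum(x$truth$is_deg),
              100 * cfg$p_deg, cfg$fold_change, sum(x$truth$up_group == "A")))
  invisible(x)
}

#' Subsample replicates per group without replacement
#'
#' Draws `n_rep` distinct samples from each group uniformly at random, the
#' resampling unit of the replicate-number sweeps. The gene set is unchanged;
#' when `n_rep` equals a group's size that whole group is returned.
#'
#' @param x an [expr_matrix()] (or the `counts` of a `sim_counts` object).
#' @param groups group labels covering the columns of `x`.
#' @param n_rep replicates to keep per group; must not exceed any group size.
#' @param seed optional integer seed.
#' @return list with `matrix` (column-subset [expr_matrix()]) and `groups`
#'   (labels restricted to the kept samples).
#' @export
subsample_replicates <- function(x, groups, n_rep, seed = NULL) {
  if (inherits(x, "sim_counts")) {
    if (missing(groups) || is.null(groups)) groups <- x$groups
    x <- x$counts
  }
  g <- .match_groups(x, groups)
  sizes <- table(g)
  if (any(n_rep > sizes))
    stop("n_rep = ", n_rep, " exceeds group size(s): ",
         paste(names(sizes)[n_rep > sizes], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(levels(g), function(h) {
    i <- which(g == h)
    sort(i[sample.int(length(i), n_rep)])
  }), use.names = FALSE)
  keep <- sort(keep)
  list(matrix = .rewrap(unclass(x)[, keep, drop = FALSE], x),
       groups = droplevels(g[keep]))
}
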