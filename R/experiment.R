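# Deterministic per-iteration seed from (master seed, n_rep, iteration),
# kept below 2^31 so it is a valid R integer seed.
.child_seed <- function(seed, n_rep, iteration) {
  as.integer((as.numeric(seed) * 48271 + n_rep * 1000003 +
                iteration * 7919) %% 2147483647)
}

#' Replicate-number sweep with bootstrap subsampling
#'
#' The simulation-study harness: for each replicate number in `n_rep_grid`
#' and each of `n_iter` iterations, draw `n_rep` samples per group without
#' replacement, filter genes, compute the average silhouette of the grouping
#' on the subsample, and run the exact NB DE test — recording P_DEG (and AUC
#' when per-gene truth is known). AS is computed on the zero-then-unique
#' filtered subsample; DE on the zero-filtered subsample. Each iteration's
#' seed is derived deterministically from (`seed`, n_rep, iteration), so any
#' single record can be re-run in isolation.
#'
#' @param x an [expr_matrix()] of counts (e.g. a simulated baseline matrix),
#'   or a `sim_counts` object (its groups and truth are then used).
#' @param groups group labels (two groups); taken from `x` if a `sim_counts`.
#' @param n_rep_grid integer vector of replicate numbers; each must not
#'   exceed the smaller group size.
#' @param n_iter bootstrap iterations per grid level (default 100).
#' @param fdr FDR threshold for P_DEG (default 0.10).
#' @param truth optional per-gene DEG truth (see [nb_exact_test()]); taken
#'   from `x` if a `sim_counts`.
#' @param norm normalization method for the DE test.
#' @param seed master integer seed.
#' @return object of class `"as_sweep"`: list with `records` (data.frame:
#'   n_rep, iteration, seed, p_deg, as_value, auc, samples) and the call
#'   configuration.
#' @examples
#' sim <- simulate_counts(n_genes = 500, p_deg = 0.2, n_rep_a = 8,
#'                        n_rep_b = 8, seed = 3)
#' sw <- run_sweep(sim, n_rep_grid = c(3, 6), n_iter = 3, seed = 11)
#' summary(sw)
#' @export
run_sweep <- function(x, groups = NULL, n_rep_grid, n_iter = 100,
                      fdr = 0.1, truth = NULL,
                      norm = c("tmm", "libsize", "degespipe"), seed = 1) {
  norm <- match.arg(norm)
  if (inherits(x, "sim_counts")) {
    if (is.null(groups)) groups <- x$groups
    if (is.null(truth)) truth <- x$truth
    x <- x$counts
  }
  g <- .match_groups(x, groups)
  sizes <- table(g)
  if (any(n_rep_grid > min(sizes)))
    stop("n_rep_grid exceeds the smallest group size (", min(sizes), ")")
  if (!is.null(truth) && is.data.frame(truth))
    truth <- stats::setNames(truth$is_deg, truth$gene_id)

  grid <- expand.grid(iteration = seq_len(n_iter), n_rep = n_rep_grid)
  rec <- lapply(seq_len(nrow(grid)), function(k) {
    n_rep <- grid$n_rep[k]; it <- grid$iteration[k]
    s <- .child_seed(seed, n_rep, it)
    sub <- subsample_replicates(x, g, n_rep, seed = s)
    zf <- filter_zero(sub$matrix)
    as_res <- score_groups(sub$matrix, sub$groups)
    tr <- if (is.null(truth)) NULL else truth[rownames(zf$matrix)]
    if (!is.null(tr) && (all(tr) || !any(tr))) tr <- NULL  # AUC undefined
    de <- nb_exact_test(zf$matrix, sub$groups, norm = norm, fdr = fdr,
                        truth = tr)
    data.frame(n_rep = n_rep, iteration = it, seed = s,
               p_deg = de$p_deg, as_value = as_res$AS, auc = de$auc,
               samples = paste(colnames(sub$matrix), collapse = ","),
               stringsAsFactors = FALSE)
  })
  structure(list(records = do.call(rbind, rec),
                 n_rep_grid = sort(unique(n_rep_grid)), n_iter = n_iter,
                 fdr = fdr, norm = norm, seed = seed,
                 has_truth = !is.null(truth)),
            class = "as_sweep")
}

#' @export
print.as_sweep <- function(x, ...) {
  cat(sprintf("Replicate-number sweep: N_rep in {%s}, %d iterations each\n",
              paste(x$n_rep_grid, collapse = ", "), x$n_iter))
  print(summary_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-level summary of a sweep
#'
#' @param x an `"as_sweep"` result.
#' @return data.frame with per-n_rep means and standard deviations of P_DEG,
#'   AS and (when available) AUC.
#' @export
summary_table <- function(x) {
  r <- x$records
  out <- do.call(rbind, lapply(split(r, r$n_rep), function(d) {
    data.frame(n_rep = d$n_rep[1],
               p_deg_mean = mean(d$p_deg), p_deg_sd = stats::sd(d$p_deg),
               as_mean = mean(d$as_value), as_sd = stats::sd(d$as_value),
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc))
  }))
  out[order(out$n_rep), , drop = FALSE]
}

#' @export
summary.as_sweep <- function(object, ...) {
  print(object)
  cat(sprintf("AS-vs-N_rep slope: %.5f per replicate\n",
              slope_as_vs_nrep(object)))
  invisible(object)
}

#' Least-squares slope of mean AS against N_rep
#'
#' Fits mean AS per replicate-number level against the level by ordinary
#' least squares. A slope near zero is the signature that the average
#' silhouette, unlike P_DEG, does not depend on the number of replicates.
#'
#' @param x an `"as_sweep"` result with >= 2 grid levels.
#' @return the slope (AS units per replicate).
#' @export
slope_as_vs_nrep <- function(x) {
  tab <- summary_table(x)
  if (nrow(tab) < 2L) stop("need >= 2 n_rep levels")
  unname(stats::coef(stats::lm(as_mean ~ n_rep, data = tab))[2L])
}

#' P_DEG vs AS across simulated true-DEG fractions
#'
#' Builds the scatter relating the declared-DEG percentage to the average
#' silhouette at a fixed small replicate number: for each true DEG fraction
#' in `p_deg_grid` and each iteration, simulate a fresh two-group dataset,
#' run the DE test and the silhouette pipeline, and record one
#' (p_simdeg, p_deg, as_value) row. Across a wide range of true fractions
#' the two measures are strongly positively correlated, and both approach 0
#' together on null data.
#'
#' @param p_deg_grid true DEG fractions in [0, 1] to simulate.
#' @param n_rep replicates per group in each simulated dataset (default 3).
#' @param n_iter datasets per grid value.
#' @param n_genes genes per dataset.
#' @param fold_change DEG effect size (default 4).
#' @param fdr FDR threshold for P_DEG.
#' @param norm normalization method for the DE test.
#' @param seed master integer seed.
#' @return data.frame: p_simdeg (percent), p_deg (percent), as_value, seed —
#'   one row per dataset.
#' @export
pdeg_as_scatter <- function(p_deg_grid, n_rep = 3, n_iter = 20,
                            n_genes = 2000, fold_change = 4, fdr = 0.1,
                            norm = c("tmm", "libsize", "degespipe"),
                            seed = 1) {
  norm <- match.arg(norm)
  grid <- expand.grid(iteration = seq_len(n_iter), p = p_deg_grid)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    pd <- grid$p[k]
    s <- .child_seed(seed, round(1000 * pd), grid$iteration[k])
    sim <- simulate_counts(n_genes = n_genes, p_deg = pd,
                           fold_change = fold_change, n_rep_a = n_rep,
                           n_rep_b = n_rep, seed = s)
    zf <- filter_zero(sim$counts)
    de <- nb_exact_test(zf$matrix, sim$groups, norm = norm, fdr = fdr)
    as_res <- score_groups(sim$counts, sim$groups)
    data.frame(p_simdeg = 100 * pd, p_deg = de$p_deg,
               as_value = as_res$AS, seed = s)
  })
  do.call(rbind, out)
}
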