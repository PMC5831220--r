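sim_fixture <- function(n_genes = 400, p_deg = 0.2, n_rep = 4, seed = 61,
                        ...) {
  simulate_counts(n_genes = n_genes, p_deg = p_deg, n_rep_a = n_rep,
                  n_rep_b = n_rep, seed = seed, ...)
}

test_that("normalization factors reflect relative depth", {
  m <- expr_matrix(matrix(rep(c(5L, 9L, 2L, 14L), 4), 4, 4,
                          dimnames = list(paste0("g", 1:4),
                                          paste0("s", 1:4))), "counts")
  expect_equal(unname(norm_factors(m, method = "libsize")), rep(1, 4))
  expect_equal(unname(norm_factors(m, method = "tmm")), rep(1, 4),
               tolerance = 1e-8)

  sim <- sim_fixture(p_deg = 0, seed = 62)
  doubled <- bare(sim$counts)
  doubled[, 1] <- doubled[, 1] * 2L
  md <- expr_matrix(doubled, "counts")
  f <- norm_factors(md, method = "libsize")
  expect_equal(unname(f[1] / f[2]),
               sum(doubled[, 1]) / sum(doubled[, 2]))

  zero <- bare(sim$counts); zero[, 2] <- 0L
  expect_error(norm_factors(expr_matrix(zero, "counts")), "zero library")
})

test_that("TMM factors are near 1 on null data and geometric mean is 1", {
  sim <- sim_fixture(n_genes = 2000, p_deg = 0, n_rep = 5, seed = 63)
  f <- norm_factors(sim$counts, method = "tmm")
  expect_true(all(abs(f - 1) < 0.05))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)
  fl <- norm_factors(sim$counts, method = "libsize")
  expect_equal(exp(mean(log(fl))), 1, tolerance = 1e-10)
})

test_that("degespipe factors stay near 1 when DEGs are balanced", {
  sim <- sim_fixture(n_genes = 800, p_deg = 0.1, n_rep = 4, seed = 64)
  f <- norm_factors(filter_zero(sim$counts)$matrix, sim$groups,
                    method = "degespipe")
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)
  expect_true(all(abs(f - 1) < 0.2))
})

test_that("the NB split p-value is 1 for a perfectly balanced observation", {
  p <- groupsil:::.nb_split_p(25, 25, 3, 3, 0.1)
  expect_equal(p, 1)
  expect_equal(groupsil:::.nb_split_p(10, 10, 4, 4, 0), 1)
})

test_that("split p-values match edgeR's small-p exact test on small totals", {
  skip_if_not_installed("edgeR")
  set.seed(65)
  for (k in 1:60) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    y_a <- matrix(rpois(n_a, 4), 1)
    y_b <- matrix(rpois(n_b, 6), 1)
    if (sum(y_a) + sum(y_b) == 0 || sum(y_a) + sum(y_b) > 50) next
    phi <- runif(1, 0.01, 1)
    ours <- groupsil:::.nb_split_p(sum(y_a), sum(y_b), n_a, n_b, phi)
    ref <- edgeR::exactTestBySmallP(y_a, y_b, dispersion = phi)
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("p-values are invariant to swapping the group labels", {
  sim <- sim_fixture(seed = 66)
  zf <- filter_zero(sim$counts)$matrix
  g <- sim$groups
  swapped <- group_labels(stats::setNames(
    ifelse(as.character(g) == "A", "B", "A"), names(g)))
  d1 <- nb_exact_test(zf, g, norm = "libsize")
  d2 <- nb_exact_test(zf, swapped, norm = "libsize")
  expect_equal(d1$table$p, d2$table$p, tolerance = 1e-12)
})

test_that("null simulations give calibrated type-I error", {
  sim <- sim_fixture(n_genes = 2000, p_deg = 0, n_rep = 5, seed = 67)
  de <- nb_exact_test(filter_zero(sim$counts)$matrix, sim$groups)
  frac <- mean(de$table$p <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches the step-down definition", {
  expect_equal(stats::p.adjust(rep(0.2, 5), "BH"), rep(0.2, 5))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(68)
  for (k in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone non-decreasing on the sorted scale
  p <- sort(runif(50))
  expect_true(all(diff(stats::p.adjust(p, "BH")) >= -1e-15))
})

test_that("q-values dominate p-values and P_DEG is monotone in the FDR", {
  sim <- sim_fixture(seed = 69)
  de <- nb_exact_test(filter_zero(sim$counts)$matrix, sim$groups,
                      truth = sim$truth)
  expect_true(all(de$table$q >= de$table$p - 1e-12))
  thresholds <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4)
  pd <- vapply(thresholds, function(f) p_deg(de, f), numeric(1))
  expect_true(all(diff(pd) >= 0))
  expect_true(all(pd >= 0 & pd <= 100))
  expect_equal(de$p_true_deg, de$p_deg * 0.9)
  expect_true(sort(de$table$rank)[1] == 1L &&
                max(de$table$rank) == nrow(de$table))
})

test_that("P_trueDEG follows the FDR identity", {
  expect_equal(round(p_true_deg(0.78, 0.40), 2), 0.47)
  expect_equal(p_true_deg(5, 0), 5)
  expect_equal(p_true_deg(0, 0.3), 0)
  expect_error(p_true_deg(0.5, 1.2), "fdr")
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  expect_equal(auc_vs_truth(c(0.001, 0.002, 0.5, 0.9),
                            c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_vs_truth(c(0.5, 0.9, 0.001, 0.002),
                            c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(auc_vs_truth(runif(5), rep(TRUE, 5)), "non-DEG")
  set.seed(70)
  for (k in 1:20) {
    n <- sample(6:30, 1)
    p <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(auc_vs_truth(p, lab), oracle_auc(p, lab),
                 tolerance = 1e-12)
  }
})

test_that("all-zero genes are excluded with a warning", {
  sim <- sim_fixture(n_genes = 50, p_deg = 0, seed = 71)
  m <- bare(sim$counts)
  m[1, ] <- 0L
  expect_warning(de <- nb_exact_test(expr_matrix(m, "counts"), sim$groups,
                                     norm = "libsize"),
                 "excluded")
  expect_equal(nrow(de$table), 49)
  expect_false("g1" %in% de$table$gene_id)
})

test_that("the engine separates a strong signal on simulated data", {
  sim <- sim_fixture(n_genes = 600, p_deg = 0.2, n_rep = 8, seed = 72)
  de <- nb_exact_test(filter_zero(sim$counts)$matrix, sim$groups,
                      truth = sim$truth)
  expect_gt(de$auc, 0.95)
  expect_gt(de$p_deg, 10)
  expect_lt(de$p_deg, 30)
})
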