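test_that("spearman distance has the forced values of rank geometry", {
  set.seed(21)
  x <- runif(30, 1, 100)
  body <- cbind(s1 = x, s2 = x, s3 = exp(x / 50), s4 = max(x) + 1 - x)
  rownames(body) <- paste0("g", 1:30)
  m <- expr_matrix(body, "continuous")
  d <- as.matrix(spearman_dist(m))
  expect_equal(d["s1", "s2"], 0)            # duplicate columns
  expect_equal(d["s1", "s3"], 0)            # monotone transform
  expect_equal(d["s1", "s4"], 2)            # reversed ranks
  expect_true(all(d >= 0 & d <= 2))
})

test_that("spearman distance equals Pearson on midranks, ties included", {
  set.seed(22)
  for (k in 1:20) {
    m <- rnd_expr_mat(50, sample(3:7, 1), lambda = 5)  # many ties
    expect_equal(as.matrix(spearman_dist(m)),
                 as.matrix(oracle_spearman_dist(bare(m))),
                 tolerance = 1e-12)
  }
})

test_that("a constant sample column is rejected by name", {
  body <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5), s3 = c(2, 1, 7))
  rownames(body) <- paste0("g", 1:3)
  m <- expr_matrix(body, "counts")
  expect_error(spearman_dist(m), "s2")
})

test_that("silhouette reproduces direct formula arithmetic", {
  dm <- matrix(0.9, 4, 4)
  dm[1, 2] <- dm[2, 1] <- dm[3, 4] <- dm[4, 3] <- 0.1
  diag(dm) <- 0
  dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- group_labels(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  res <- group_silhouette(as.dist(dm), g)
  expect_equal(res$samples$s, rep((0.9 - 0.1) / 0.9, 4))
  expect_equal(res$AS, 0.8 / 0.9)
  expect_equal(unname(res$group_means), rep(0.8 / 0.9, 2))

  # u_i = v_i everywhere -> all zero
  dm2 <- matrix(0.5, 4, 4); diag(dm2) <- 0
  dimnames(dm2) <- dimnames(dm)
  res2 <- group_silhouette(as.dist(dm2), g)
  expect_equal(res2$samples$s, rep(0, 4))
  expect_equal(res2$AS, 0)
})

test_that("silhouette matches the brute-force definition on random cases", {
  set.seed(23)
  for (k in 1:25) {
    n <- sample(5:10, 1)
    n_groups <- sample(2:3, 1)
    dm <- rnd_dist(n)
    g <- factor(sample(LETTERS[1:n_groups], n, replace = TRUE))
    if (length(unique(g)) < 2) next
    names_g <- stats::setNames(as.character(g), rownames(dm))
    res <- group_silhouette(as.dist(dm), group_labels(names_g))
    expect_equal(res$samples$s, oracle_silhouette(dm, as.character(g)),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package on 2-group cases", {
  skip_if_not_installed("cluster")
  set.seed(24)
  for (k in 1:10) {
    n <- sample(6:12, 1)
    dm <- rnd_dist(n)
    g <- c(rep(1, floor(n / 2)), rep(2, ceiling(n / 2)))
    sil <- cluster::silhouette(g, dmatrix = dm)
    res <- group_silhouette(
      as.dist(dm),
      group_labels(stats::setNames(as.character(g), rownames(dm))))
    expect_equal(res$samples$s, unname(sil[, "sil_width"]),
                 tolerance = 1e-10)
  }
})

test_that("AS is invariant to sample permutation and group relabeling", {
  set.seed(25)
  dm <- rnd_dist(8)
  g <- stats::setNames(rep(c("A", "B"), each = 4), rownames(dm))
  base <- group_silhouette(as.dist(dm), group_labels(g))
  perm <- sample(8)
  dmp <- dm[perm, perm]
  gp <- g[rownames(dmp)]
  expect_equal(group_silhouette(as.dist(dmp), group_labels(gp))$AS, base$AS)
  g2 <- stats::setNames(ifelse(g == "A", "grp_x", "grp_y"), names(g))
  expect_equal(group_silhouette(as.dist(dm), group_labels(g2))$AS, base$AS)
})

test_that("random labels on exchangeable samples give mean AS near zero", {
  set.seed(26)
  dm <- rnd_dist(10)
  draws <- replicate(250, {
    g <- stats::setNames(sample(rep(c("A", "B"), each = 5)), rownames(dm))
    group_silhouette(as.dist(dm), group_labels(g))$AS
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se + 1e-9)
})

test_that("singleton groups score zero by convention", {
  dm <- rnd_dist(4)
  g <- stats::setNames(c("A", "B", "B", "B"), rownames(dm))
  res <- group_silhouette(as.dist(dm), group_labels(g))
  expect_equal(res$samples$s[1], 0)
  expect_true(all(is.finite(res$samples$s)))
})

test_that("group distance summary matches pair enumeration", {
  dm <- matrix(c(0, 0.5, 0.7, 0.5, 0, 0.9, 0.7, 0.9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- group_labels(c(a = "G", b = "G", c = "H"))
  s0 <- group_distance_summary(as.dist(dm), g)
  expect_equal(unname(s0$intra["G"]), 0.5)   # pair of 2 at distance 0.5
  expect_true(is.na(s0$intra["H"]))          # singleton: undefined

  set.seed(27)
  for (k in 1:10) {
    n <- sample(6:10, 1)
    dm <- rnd_dist(n)
    g <- stats::setNames(sample(c("A", "B", "C"), n, replace = TRUE),
                         rownames(dm))
    if (length(unique(g)) < 2) next
    s <- group_distance_summary(as.dist(dm), group_labels(g))
    intra_o <- oracle_group_distances(dm, unname(g))
    expect_equal(s$intra[names(intra_o)], intra_o, tolerance = 1e-12)
    for (r in seq_len(nrow(s$inter))) {
      i <- which(g == s$inter$group_a[r]); j <- which(g == s$inter$group_b[r])
      expect_equal(s$inter$mean_distance[r], mean(dm[i, j, drop = FALSE]))
    }
  }
})

test_that("constant distances give equal intra and inter means", {
  dm <- matrix(0.3, 6, 6); diag(dm) <- 0
  dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- group_labels(stats::setNames(rep(c("A", "B"), each = 3),
                                    rownames(dm)))
  s <- group_distance_summary(as.dist(dm), g)
  expect_equal(unname(s$intra), c(0.3, 0.3))
  expect_equal(s$inter$mean_distance, 0.3)
})
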