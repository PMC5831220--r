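# Fixture generators and independent brute-force oracles used across the
# suite. Oracles deliberately use naive enumeration / double loops so they
# share no code path with the package implementation.

rnd_expr_mat <- function(n_genes, n_samples, type = "counts",
                         lambda = 20) {
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (type == "continuous") m <- m + matrix(runif(length(m)), nrow(m))
  expr_matrix(m, type)
}

rnd_dist <- function(n, ids = paste0("s", seq_len(n))) {
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  dm[upper.tri(dm)] <- runif(n * (n - 1) / 2, 0.05, 1.9)
  dm + t(dm)
}

# Rousseeuw's definition computed sample-by-sample with explicit loops,
# clusters taken as the given groups.
oracle_silhouette <- function(dm, g) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(g == g[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    u <- mean(sapply(own, function(j) dm[i, j]))
    v <- Inf
    for (h in unique(g)) {
      if (h == g[i]) next
      v <- min(v, mean(sapply(which(g == h), function(j) dm[i, j])))
    }
    s[i] <- if (max(u, v) == 0) 0 else (v - u) / max(u, v)
  }
  s
}

# Pearson correlation of midranks, pair by pair.
oracle_spearman_dist <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d[i, j] <- 1 - cor(rank(m[, i]), rank(m[, j]), method = "pearson")
  }
  as.dist(d)
}

# Naive O(n^3) UPGMA: rescan the full current distance matrix at every
# merge, cluster distance = unweighted mean over all cross pairs of leaves.
oracle_upgma_heights <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d_ab <- mean(dm[clusters[[a]], clusters[[b]]])
      if (d_ab < bestd) { bestd <- d_ab; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Benjamini-Hochberg by the definition: q_i = min over j with p_j >= p_i of
# p_j * m / rank(p_j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[o[j]] >= p[o[i]]) cand <- min(cand, p[o[j]] * m / j)
    }
    q[o[i]] <- min(cand, 1)
  }
  q
}

# Pairwise Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(p, is_deg) {
  pos <- p[is_deg]; neg <- p[!is_deg]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Mean intra/inter group distances by explicit pair enumeration.
oracle_group_distances <- function(dm, g) {
  lev <- unique(g)
  intra <- sapply(lev, function(h) {
    i <- which(g == h)
    if (length(i) < 2) return(NA_real_)
    vals <- c()
    for (a in i) for (b in i) if (a < b) vals <- c(vals, dm[a, b])
    mean(vals)
  })
  names(intra) <- lev
  intra
}

# strip the expr_mat class/attribute for plain-matrix comparisons
bare <- function(x) {
  x <- unclass(x)
  attr(x, "value_type") <- NULL
  x
}
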