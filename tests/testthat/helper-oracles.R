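# Independent oracles used by the tests.  These deliberately reimplement the
# quantities with the most naive approach available (double loops, explicit
# enumeration) and stay independent of the package code paths they check.

# density by explicit double loop over node pairs
oracle_density <- function(adj) {
  n <- nrow(adj)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) e <- e + (adj[i, j] != 0)
  }
  2 * e / (n * (n - 1))
}

# Newman modularity of one partition, via the elementwise double-sum form
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]
oracle_modularity <- function(adj, membership) {
  m2 <- sum(adj)            # 2m
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - deg[i] * deg[j] / m2
      }
    }
  }
  q / m2
}

# all set partitions of 1..n, built recursively (element i joins an existing
# block or starts a new one) -- independent of the package's iterative
# restricted-growth-string enumeration
oracle_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, b)
    }
  }
  out
}

# maximum modularity by exhaustive search over all partitions
oracle_best_modularity <- function(adj) {
  best <- -Inf
  for (p in oracle_partitions(nrow(adj))) {
    q <- oracle_modularity(adj, p)
    if (q > best) best <- q
  }
  best
}

# Mann-Whitney rank estimator of the AUC (ties counted half)
oracle_rank_auc <- function(scores, labels) {
  s1 <- scores[as.logical(labels)]
  s0 <- scores[!as.logical(labels)]
  tot <- 0
  for (a in s1) {
    for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# mean silhouette width per cluster from coordinates (small n only)
oracle_silhouette_by_cluster <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  labs <- unique(labels)
  sil <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  tapply(sil, labels, mean)
}

# random symmetric 0/1 adjacency matrix on n nodes
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}

# immune_network object from a bare adjacency matrix (all edges positive)
network_from_adjacency <- function(adj, group = "test") {
  n <- nrow(adj)
  r <- adj * 0.9
  p <- matrix(ifelse(adj > 0, 1e-6, 0.9), n, n)
  diag(r) <- 1; diag(p) <- NA
  colnames(r) <- rownames(r) <- paste0("s", seq_len(n))
  build_network(r, p, threshold = 0.6, alpha_edge = 0.05, group = group)
}
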