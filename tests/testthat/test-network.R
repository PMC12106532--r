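# Correlation networks: edge rule, density, modularity, signs, layout.

test_that("group correlations are symmetric with sane diagonals", {
  f <- simulate_frequencies(default_scenario(), seed = 71)
  gc <- group_correlations(f, "healthy")
  expect_lt(max(abs(gc$r - t(gc$r))), 1e-12)
  expect_equal(unname(diag(gc$r)), rep(1, ncol(f$freq)))
  expect_true(all(is.na(diag(gc$p))))
  # identical columns correlate exactly
  x <- cbind(a = rnorm(10, 10), b = 0)
  x[, "b"] <- x[, "a"]
  colnames(x) <- c("a", "b")
  rownames(x) <- sprintf("s%d", 1:10)
  f2 <- subset_frequencies(x, setNames(rep("healthy", 10), rownames(x)))
  expect_equal(group_correlations(f2, "healthy")$r["a", "b"], 1)
  # zero-variance subsets warn and give NA
  x3 <- cbind(a = rnorm(10, 10), b = 5)
  rownames(x3) <- sprintf("s%d", 1:10)
  f3 <- subset_frequencies(x3, setNames(rep("healthy", 10), rownames(x3)))
  expect_warning(gc3 <- group_correlations(f3, "healthy"), "zero-variance")
  expect_true(is.na(gc3$r["a", "b"]))
  # too few subjects rejected
  f4 <- subset_frequencies(x3[1:3, ],
                           setNames(rep("healthy", 3), rownames(x3)[1:3]))
  expect_error(group_correlations(f4, "healthy"), "fewer than 4")
})

test_that("a planted correlation is recovered at moderate n", {
  sc <- block_scenario()
  comp <- simulate_compositions(sc$scenario, "healthy", n = 200, seed = 72)
  f <- subset_frequencies(100 * comp,
                          setNames(rep("healthy", 200),
                                   sprintf("h%03d", 1:200)))
  gc <- group_correlations(f, "healthy")
  expect_lt(abs(gc$r[2, 3] - 0.8), 0.1)
})

test_that("the edge rule is strict on |r| and requires significance", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.6       # exactly at threshold: no edge
  r[1, 3] <- r[3, 1] <- -0.7      # negative edge
  r[2, 4] <- r[4, 2] <- 0.9       # insignificant: no edge
  colnames(r) <- rownames(r) <- paste0("s", 1:4)
  p <- matrix(1e-4, 4, 4); diag(p) <- NA
  p[2, 4] <- p[4, 2] <- 0.2
  net <- build_network(r, p, threshold = 0.6, alpha_edge = 0.05)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$r, -0.7)
  expect_identical(net$edges$sign, "negative")
  expect_error(build_network(r, p, threshold = 1.2), "\\[0, 1\\)")
  # nothing above threshold: empty edge set, zero density
  r0 <- diag(4); colnames(r0) <- rownames(r0) <- paste0("s", 1:4)
  p0 <- matrix(1e-4, 4, 4); diag(p0) <- NA
  net0 <- build_network(r0, p0)
  s0 <- summarize_network(net0)
  expect_equal(s0$E, 0L)
  expect_equal(s0$density, 0)
  expect_equal(s0$modularity, 0)
  expect_true(s0$no_edges)
})

test_that("summary statistics follow their closed forms", {
  # complete graph on 4 nodes: density 1
  k4 <- network_from_adjacency(matrix(1, 4, 4) - diag(4))
  s4 <- summarize_network(k4)
  expect_equal(s4$density, 1)
  expect_equal(s4$isolated, 0L)
  # 46 nodes with 107 edges reproduce the reference density
  set.seed(73)
  a46 <- matrix(0L, 46, 46)
  pairs <- which(upper.tri(a46))
  on <- sample(pairs, 107)
  a46[on] <- 1L
  a46 <- a46 + t(a46)
  s46 <- summarize_network(network_from_adjacency(a46))
  expect_equal(s46$E, 107L)
  expect_equal(s46$density, 2 * 107 / (46 * 45))
  expect_equal(round(s46$density, 3), 0.103)
  # two disjoint triangles split into two communities with Q = 0.5
  tri2 <- matrix(0L, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1L
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1L
  tri2 <- tri2 + t(tri2)
  s_tri <- summarize_network(network_from_adjacency(tri2))
  expect_equal(s_tri$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(s_tri$membership)), 2L)
  # any single-community graph has Q = 0: a clique cannot be split
  k5 <- network_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_equal(summarize_network(k5)$modularity, 0, tolerance = 1e-12)
  expect_error(summarize_network(network_from_adjacency(matrix(0, 1, 1))),
               "fewer than 2")
})

test_that("density and modularity match brute force on small graphs", {
  set.seed(74)
  for (n in 4:7) {
    for (rep in 1:4) {
      adj <- random_adjacency(n, p = 0.45)
      net <- network_from_adjacency(adj)
      s <- summarize_network(net)
      expect_equal(s$density, oracle_density(adj))
      expect_equal(s$modularity, oracle_best_modularity(adj),
                   tolerance = 1e-12)
      expect_equal(oracle_modularity(adj, s$membership), s$modularity,
                   tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold never adds edges", {
  f <- simulate_frequencies(default_scenario(), seed = 75)
  gc <- group_correlations(f, "healthy")
  prev_e <- Inf
  for (thr in c(0.3, 0.5, 0.6, 0.8)) {
    e <- nrow(build_network(gc, threshold = thr)$edges)
    expect_lte(e, prev_e)
    prev_e <- e
  }
})

test_that("edge signs survive from the correlation matrix to the summary", {
  sc <- block_scenario()
  comp <- simulate_compositions(sc$scenario, "healthy", n = 200, seed = 76)
  f <- subset_frequencies(100 * comp,
                          setNames(rep("healthy", 200),
                                   sprintf("h%03d", 1:200)))
  gc <- group_correlations(f, "healthy")
  net <- build_network(gc, group = "healthy")
  s <- summarize_network(net)
  neg_edges <- net$edges[net$edges$sign == "negative", ]
  expect_equal(s$negative_edges, nrow(neg_edges))
  expect_true(all(neg_edges$r < 0))
  for (k in seq_len(nrow(neg_edges))) {
    expect_lt(gc$r[neg_edges$from[k], neg_edges$to[k]], 0)
  }
})

test_that("network comparison reports deltas and lineage mixing", {
  k4 <- network_from_adjacency(matrix(1, 4, 4) - diag(4))
  cmp0 <- compare_networks(k4, k4)
  expect_equal(cmp0$delta_density, 0)
  expect_equal(cmp0$delta_modularity, 0)
  expect_equal(cmp0$delta_negative_edges, 0)
  other <- network_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_error(compare_networks(k4, other), "node sets differ")
  lineage <- setNames(c("T", "T", "B", "B"), k4$nodes)
  cmp <- compare_networks(k4, k4, lineage = lineage)
  expect_equal(unname(cmp$same_lineage_fraction["healthy"]), 2 / 6)
})

test_that("the observed density contrast escapes the permutation null", {
  # a single cohort at n = 39/19 has moderate power, so the property is
  # checked as a majority over a few simulated cohorts
  sc <- default_scenario()
  rejected <- vapply(1:5, function(s) {
    f <- simulate_frequencies(sc, seed = 100 + s)
    pt <- density_permutation_test(f, n_perm = 100, seed = 200 + s)
    pt$observed > pt$quantiles[2] || pt$observed < pt$quantiles[1]
  }, logical(1))
  expect_gte(sum(rejected), 3L)
})

test_that("layouts are seeded and respect connectivity", {
  # empty graph: every node on the ring
  empty <- network_from_adjacency(matrix(0L, 6, 6))
  lay0 <- layout_network(empty, seed = 1)
  expect_equal(unname(sqrt(rowSums(lay0^2))), rep(max(sqrt(rowSums(lay0^2))), 6),
               tolerance = 1e-9)
  # determinism
  sc <- block_scenario()
  comp <- simulate_compositions(sc$scenario, "healthy", n = 200, seed = 79)
  f <- subset_frequencies(100 * comp,
                          setNames(rep("healthy", 200),
                                   sprintf("h%03d", 1:200)))
  net <- build_network(group_correlations(f, "healthy"), group = "healthy")
  l1 <- layout_network(net, seed = 5)
  l2 <- layout_network(net, seed = 5)
  expect_identical(l1, l2)
  # connected pairs sit closer than unconnected pairs on average
  d <- as.matrix(dist(l1))
  adj <- matrix(0, length(net$nodes), length(net$nodes),
                dimnames = list(net$nodes, net$nodes))
  adj[cbind(net$edges$from, net$edges$to)] <- 1
  adj <- adj + t(adj)
  up <- upper.tri(adj)
  expect_lt(mean(d[up][adj[up] == 1]), mean(d[up][adj[up] == 0]))
})

test_that("graphml and edge-list exports are written", {
  k4 <- network_from_adjacency(matrix(1, 4, 4) - diag(4))
  g <- tempfile(fileext = ".graphml")
  e <- tempfile(fileext = ".tsv")
  write_network_graphml(k4, g)
  write_edge_list(k4, e)
  expect_true(file.size(g) > 0)
  el <- read.table(e, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 6L)
})
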