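# Per-group signed correlation networks over subsets, with density,
# modularity, negative-edge statistics and a force-directed layout.

#' Pairwise subset-frequency correlations within one group
#'
#' Pearson (default) or Spearman correlations of subset frequencies across
#' the subjects of one group, with two-sided p-values from the t
#' approximation.  Zero-variance subsets get `NA` correlations (absent
#' edges) with a warning.
#'
#' @param freqs a `subset_frequencies` object.
#' @param group `"healthy"` or `"sepsis"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` (correlation matrix, unit diagonal), `p` (two-sided
#'   p matrix, `NA` diagonal), `n` (subjects used), `group`.
#' @export
group_correlations <- function(freqs, group = c("healthy", "sepsis"),
                               method = c("pearson", "spearman")) {
  group <- match.arg(group)
  method <- match.arg(method)
  x <- freqs$freq[freqs$group == group, , drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop("group '", group, "' has fewer than 4 subjects",
                  call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds <= 1e-12)) {
    warning("zero-variance subset(s); correlations undefined: ",
            paste(colnames(x)[sds <= 1e-12], collapse = ", "),
            call. = FALSE)
  }
  r <- suppressWarnings(cor(x, method = method))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(r) <- 1
  diag(p) <- NA_real_
  list(r = r, p = p, n = n, group = group, method = method)
}

#' Build a signed immune network from a correlation matrix
#'
#' Subsets are connected when the absolute correlation strictly exceeds the
#' threshold (default 0.6) and the two-sided p-value is below `alpha_edge`
#' (default 0.05, so every represented correlation is statistically
#' significant).  All subsets stay in the node set whether or not they gain
#' edges; edge weights keep the correlation's sign (positive vs negative
#' interaction).
#'
#' @param corr correlation matrix (or the list from
#'   [group_correlations()], in which case `p` is taken from it).
#' @param p matching p-value matrix.
#' @param threshold minimum absolute correlation, in `[0, 1)`; the
#'   inequality is strict.
#' @param alpha_edge edge significance level.
#' @param group group label carried on the network.
#' @return object of class `immune_network`: `group`, `nodes`, `edges`
#'   (data.frame `from`, `to`, `r`, `p`, `sign`), `threshold`, `alpha_edge`.
#' @export
build_network <- function(corr, p = NULL, threshold = 0.6,
                          alpha_edge = 0.05, group = NA_character_) {
  if (is.list(corr) && !is.matrix(corr)) {
    p <- p %||% corr$p
    if (is.na(group)) group <- corr$group %||% NA_character_
    corr <- corr$r
  }
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            !is.null(p), all(dim(p) == dim(corr)))
  nodes <- colnames(corr) %||% paste0("s", seq_len(ncol(corr)))
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  rv <- corr[idx]; pv <- p[idx]
  keep <- !is.na(rv) & !is.na(pv) & abs(rv) > threshold & pv < alpha_edge
  edges <- data.frame(
    from = nodes[idx[keep, 1]],
    to = nodes[idx[keep, 2]],
    r = rv[keep],
    p = pv[keep],
    sign = ifelse(rv[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(
    list(group = group, nodes = nodes, edges = edges,
         threshold = threshold, alpha_edge = alpha_edge),
    class = "immune_network"
  )
}

#' @export
print.immune_network <- function(x, ...) {
  cat("<immune_network> ", x$group, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$sign == "negative"),
      " negative), |r| > ", x$threshold, "\n", sep = "")
  invisible(x)
}

# 0/1 adjacency matrix of a network (signs stripped)
.network_adjacency <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

.network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "r", "p", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Newman modularity of a partition
#'
#' `Q = sum_c (e_c / m - (K_c / 2m)^2)` on the unweighted, sign-stripped
#' graph: the fraction of edges inside communities minus its
#' degree-preserving expectation.  `Q = 0` when the graph has no edges.
#'
#' @param adjacency symmetric 0/1 matrix.
#' @param membership integer community id per node.
#' @return modularity value in `[-0.5, 1]`.
#' @export
modularity_value <- function(adjacency, membership) {
  m <- sum(adjacency) / 2
  if (m == 0) return(0)
  deg <- rowSums(adjacency)
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_c <- sum(adjacency[in_c, in_c, drop = FALSE]) / 2
    k_c <- sum(deg[in_c])
    q <- q + e_c / m - (k_c / (2 * m))^2
  }
  q
}

# Enumerate set partitions of 1..n as restricted growth strings, applying
# `fn` to each membership vector.  Used for exact modularity maximisation on
# small graphs.
.for_each_partition <- function(n, fn) {
  a <- integer(n)
  repeat {
    fn(a)
    # find the rightmost position that can still be incremented: a[i] may
    # rise to at most max(a[1..i-1]) + 1 (restricted growth condition)
    i <- n
    while (i > 1L && a[i] >= max(a[seq_len(i - 1L)]) + 1L) i <- i - 1L
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 0L
  }
  invisible(NULL)
}

# Best-modularity partition: exact exhaustive search when at most
# `exact_max` non-isolated nodes (isolated nodes cannot change Q), otherwise
# deterministic greedy agglomeration (fast-greedy).
.best_partition <- function(adjacency, exact_max = 8L) {
  n <- nrow(adjacency)
  deg <- rowSums(adjacency)
  active <- which(deg > 0)
  if (length(active) == 0) {
    return(list(membership = seq_len(n), q = 0, method = "none"))
  }
  if (length(active) <= exact_max) {
    sub <- adjacency[active, active, drop = FALSE]
    best_q <- -Inf
    best <- NULL
    .for_each_partition(length(active), function(a) {
      q <- modularity_value(sub, a)
      if (q > best_q + 1e-12) {
        best_q <<- q
        best <<- a
      }
    })
    membership <- seq_len(n) + max(best) + 1L
    membership[active] <- best
    return(list(membership = membership, q = best_q, method = "exact"))
  }
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  cm <- igraph::cluster_fast_greedy(g)
  membership <- igraph::membership(cm)
  list(membership = as.integer(membership),
       q = modularity_value(adjacency, as.integer(membership)),
       method = "greedy")
}

#' Summary statistics of an immune network
#'
#' Node count `n` (isolated subsets included), edge count `E`, density
#' `D = 2E / (n (n-1))`, the count and fraction of negative edges (reported
#' as 0 with a flag when there are no edges), isolated-node count, and
#' modularity `Q` with its community partition.  `Q` is computed on the
#' unweighted, sign-stripped graph; the partition maximising `Q` is found
#' exactly (exhaustive search) when at most `exact_max` nodes carry edges
#' and by deterministic greedy agglomeration otherwise.
#'
#' @param net an `immune_network`.
#' @param exact_max node-count bound for the exact modularity search.
#' @return object of class `network_summary`: `group`, `n`, `E`, `density`,
#'   `negative_edges`, `negative_fraction`, `no_edges` flag, `isolated`,
#'   `modularity`, `membership`, `modularity_method`.
#' @export
summarize_network <- function(net, exact_max = 8L) {
  n <- length(net$nodes)
  if (n < 2) stop("density undefined for fewer than 2 nodes", call. = FALSE)
  e <- nrow(net$edges)
  adj <- .network_adjacency(net)
  neg <- sum(net$edges$sign == "negative")
  part <- .best_partition(adj, exact_max = exact_max)
  structure(
    list(
      group = net$group, n = n, E = e,
      density = 2 * e / (n * (n - 1)),
      negative_edges = neg,
      negative_fraction = if (e > 0) neg / e else 0,
      no_edges = e == 0,
      isolated = sum(rowSums(adj) == 0),
      modularity = part$q,
      membership = part$membership,
      modularity_method = part$method
    ),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> ", x$group, ": n=", x$n, " E=", x$E,
      " D=", round(x$density, 4), " negatives=", x$negative_edges,
      " (", round(100 * x$negative_fraction, 2), "%) Q=",
      round(x$modularity, 4), " isolated=", x$isolated, "\n", sep = "")
  invisible(x)
}

#' Contrast two immune networks over the same node set
#'
#' Reports the healthy-minus-sepsis differences in density, modularity and
#' negative-edge statistics, and -- when a lineage map is supplied -- the
#' fraction of each network's edges whose endpoints share a lineage (the
#' computable form of a "restricted communication module" between related
#' T-cell subsets versus cross-lineage communication in health).
#'
#' @param healthy,sepsis `immune_network` objects on the same node set.
#' @param lineage optional named character vector mapping node names to
#'   lineages.
#' @return list with both `network_summary` objects, `delta_density`,
#'   `delta_modularity`, `delta_negative_edges`, `delta_negative_fraction`,
#'   and per-group `same_lineage_fraction` (NA without a lineage map).
#' @export
compare_networks <- function(healthy, sepsis, lineage = NULL) {
  if (!identical(sort(healthy$nodes), sort(sepsis$nodes))) {
    stop("node sets differ between the two networks", call. = FALSE)
  }
  sh <- summarize_network(healthy)
  ss <- summarize_network(sepsis)
  same_lin <- function(net) {
    if (is.null(lineage) || nrow(net$edges) == 0) return(NA_real_)
    mean(lineage[net$edges$from] == lineage[net$edges$to])
  }
  list(
    healthy = sh, sepsis = ss,
    delta_density = sh$density - ss$density,
    delta_modularity = sh$modularity - ss$modularity,
    delta_negative_edges = sh$negative_edges - ss$negative_edges,
    delta_negative_fraction = sh$negative_fraction - ss$negative_fraction,
    same_lineage_fraction = c(healthy = same_lin(healthy),
                              sepsis = same_lin(sepsis))
  )
}

#' Permutation test for the density contrast
#'
#' Permutes group labels across subjects, rebuilds both networks, and
#' returns the permutation distribution of the density difference
#' (healthy - sepsis) together with the observed value.
#'
#' @param freqs a `subset_frequencies` object.
#' @param n_perm number of permutations (default 200).
#' @param threshold,alpha_edge edge rule (see [build_network()]).
#' @param seed integer seed.
#' @return list with `observed`, `perm` (vector), and the two-sided
#'   `quantiles` (2.5% and 97.5%).
#' @export
density_permutation_test <- function(freqs, n_perm = 200L, threshold = 0.6,
                                     alpha_edge = 0.05, seed = 1L) {
  delta_d <- function(grp) {
    f <- subset_frequencies(freqs$freq, grp)
    dh <- summarize_network(build_network(
      group_correlations(f, "healthy"), threshold = threshold,
      alpha_edge = alpha_edge, group = "healthy"))$density
    ds <- summarize_network(build_network(
      group_correlations(f, "sepsis"), threshold = threshold,
      alpha_edge = alpha_edge, group = "sepsis"))$density
    dh - ds
  }
  observed <- delta_d(freqs$group)
  perm <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(i) {
      delta_d(setNames(sample(freqs$group), names(freqs$group)))
    }, numeric(1))
  })
  list(observed = observed, perm = perm,
       quantiles = quantile(perm, c(0.025, 0.975)))
}

#' Force-directed layout of an immune network
#'
#' Seeded Fruchterman-Reingold layout of the connected part; isolated nodes
#' are placed deterministically on a surrounding ring.
#'
#' @param net an `immune_network`.
#' @param seed integer seed.
#' @return matrix (nodes x 2) of coordinates, row names = node names.
#' @export
layout_network <- function(net, seed = 1L) {
  g <- .network_igraph(net)
  coords <- with_seed_opt(seed, igraph::layout_with_fr(g))
  rownames(coords) <- net$nodes
  deg <- igraph::degree(g)
  iso <- which(deg == 0)
  if (length(iso)) {
    rad <- 1.2 * max(abs(coords[deg > 0, ]), 1)
    theta <- 2 * pi * (seq_along(iso) - 1) / length(iso)
    coords[iso, ] <- rad * cbind(cos(theta), sin(theta))
  }
  coords
}

#' Export an immune network to GraphML
#'
#' @param net an `immune_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(.network_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write the edge list of an immune network to TSV
#'
#' @param net an `immune_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
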