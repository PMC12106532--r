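# SOM metaclustering, mixed-cluster exclusion, subset frequencies and the
# scaled-median expression heatmap.

#' Clustering configuration
#'
#' @param grid_rows,grid_cols SOM grid (default 10 x 10).
#' @param n_metaclusters metacluster count after merging (default 47).
#' @param linkage agglomeration linkage for codebook merging (default
#'   `"average"`).
#' @param som_epochs SOM training rounds.
#' @param repeats reseeded refits for the stability assessment.
#' @param mixed_threshold scaled-median co-expression threshold for the
#'   mixed-cluster rule (default 0.5).
#' @param seed integer seed.
#' @return list of class `clustering_config`.
#' @export
clustering_config <- function(grid_rows = 10L, grid_cols = 10L,
                              n_metaclusters = 47L,
                              linkage = c("average", "ward", "complete"),
                              som_epochs = 14L, repeats = 1L,
                              mixed_threshold = 0.5, seed = 1L) {
  linkage <- match.arg(linkage)
  stopifnot(grid_rows * grid_cols >= n_metaclusters, repeats >= 1)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_metaclusters = as.integer(n_metaclusters),
         linkage = linkage, som_epochs = as.integer(som_epochs),
         repeats = as.integer(repeats), mixed_threshold = mixed_threshold,
         seed = as.integer(seed)),
    class = "clustering_config"
  )
}

#' Fit the SOM stage of the clustering pipeline
#'
#' Thin wrapper around [som_fit()] taking a `clustering_config`; returns a
#' `cluster_model` holding the codebook and per-event node assignment, ready
#' for [metacluster()].
#'
#' @param pooled a `pooled_events` object (asinh scale) or numeric matrix.
#' @param config a [clustering_config()].
#' @return object of class `cluster_model`.
#' @export
fit_som <- function(pooled, config = clustering_config()) {
  som <- som_fit(pooled,
                 grid_rows = config$grid_rows, grid_cols = config$grid_cols,
                 epochs = config$som_epochs, seed = config$seed)
  structure(
    list(som = som, codebook = som$codebook,
         node_assignment = som$assignment,
         node_to_metacluster = NULL, excluded_metaclusters = integer(0),
         subset_labels = NULL, config = config),
    class = "cluster_model"
  )
}

#' Merge SOM nodes into metaclusters
#'
#' Hierarchical agglomerative clustering of the codebook vectors (Euclidean
#' distance, configurable linkage) cut at `n_metaclusters` groups.
#' Deterministic given the fitted codebook.  Metaclustering is a coarsening:
#' all events of one node stay together.
#'
#' @param model a `cluster_model` from [fit_som()].
#' @param n_metaclusters number of metaclusters (default from the config).
#' @return the model with `node_to_metacluster` filled in.
#' @export
metacluster <- function(model, n_metaclusters = model$config$n_metaclusters) {
  m <- nrow(model$codebook)
  if (n_metaclusters > m) {
    stop("n_metaclusters (", n_metaclusters, ") exceeds node count (", m,
         ")", call. = FALSE)
  }
  method <- switch(model$config$linkage,
                   average = "average", ward = "ward.D2",
                   complete = "complete")
  # cluster the codebook vectors of populated nodes; nodes that captured no
  # events inherit the metacluster of their nearest populated node, so every
  # node maps to exactly one metacluster and no metacluster is empty
  occupied <- sort(unique(model$node_assignment))
  if (n_metaclusters > length(occupied)) {
    stop("n_metaclusters (", n_metaclusters, ") exceeds the number of ",
         "populated nodes (", length(occupied), ")", call. = FALSE)
  }
  hc <- hclust(dist(model$codebook[occupied, , drop = FALSE]),
               method = method)
  cut_occ <- cutree(hc, k = n_metaclusters)
  mapping <- integer(m)
  mapping[occupied] <- cut_occ
  empty <- setdiff(seq_len(m), occupied)
  if (length(empty)) {
    nn <- .nearest_node(model$codebook[empty, , drop = FALSE],
                        model$codebook[occupied, , drop = FALSE])
    mapping[empty] <- cut_occ[nn]
  }
  model$node_to_metacluster <- mapping
  model$metacluster_hclust <- hc
  model
}

# per-event metacluster ids
.meta_assignment <- function(model) {
  if (is.null(model$node_to_metacluster)) {
    stop("run metacluster() first", call. = FALSE)
  }
  model$node_to_metacluster[model$node_assignment]
}

#' Scaled median marker expression per metacluster
#'
#' Per-metacluster, per-marker median of the (asinh-scale) intensities,
#' min-max scaled to [0, 1] within each marker across metaclusters -- the
#' values a dendrogram heatmap displays.  A marker constant across
#' metaclusters has no scale; it is emitted as 0 with a warning.
#'
#' @param model a metaclustered `cluster_model`.
#' @param pooled the `pooled_events` the model was fitted to.
#' @param scaled if `FALSE`, return the raw medians.
#' @return list with `medians` and `scaled` (metaclusters x markers
#'   matrices), plus `row_order`/`col_order` dendrogram orderings.
#' @export
expression_heatmap <- function(model, pooled, scaled = TRUE) {
  meta <- .meta_assignment(model)
  x <- if (inherits(pooled, "pooled_events")) pooled$exprs else pooled
  ks <- sort(unique(model$node_to_metacluster))
  med <- matrix(NA_real_, length(ks), ncol(x),
                dimnames = list(paste0("mc", ks), colnames(x)))
  for (i in seq_along(ks)) {
    rows <- meta == ks[i]
    if (!any(rows)) {
      stop("metacluster ", ks[i], " has no events; median undefined",
           call. = FALSE)
    }
    med[i, ] <- apply(x[rows, , drop = FALSE], 2L, median)
  }
  rng <- apply(med, 2L, range)
  span <- rng[2, ] - rng[1, ]
  sc <- sweep(med, 2L, rng[1, ])
  const <- span <= 1e-12
  if (any(const)) {
    warning("constant marker(s) across metaclusters scaled to 0: ",
            paste(colnames(med)[const], collapse = ", "), call. = FALSE)
    span[const] <- 1
    sc[, const] <- 0
  }
  sc <- sweep(sc, 2L, span, `/`)
  out <- list(medians = med, scaled = sc,
              row_order = hclust(dist(sc))$order,
              col_order = hclust(dist(t(sc)))$order)
  if (!scaled) out$scaled <- NULL
  out
}

#' Flag metaclusters that look like mixed cell populations
#'
#' A metacluster is flagged when its scaled median expression is
#' simultaneously above the threshold on two markers of a mutually exclusive
#' lineage pair (defaults: CD3/CD19, CD3/CD14, CD14/CD56) -- the rule-based
#' analogue of excluding a doublet-like mixed cluster by inspection.
#'
#' @param model a metaclustered `cluster_model`.
#' @param pooled the `pooled_events` used for fitting.
#' @param pairs 2-column character matrix of exclusive marker pairs
#'   (default: the panel pairs in [default_marker_panel()]).
#' @param threshold scaled-median threshold (default from the config, 0.5).
#' @param min_frac smallest fraction of pooled events a metacluster must
#'   hold to be eligible for exclusion (default 0.001): a scaled median over
#'   a handful of events is too unstable to call a mixed phenotype.
#' @return the model with `excluded_metaclusters` set (integer ids).
#' @export
flag_mixed <- function(model, pooled,
                       pairs = default_marker_panel()$exclusive_pairs,
                       threshold = model$config$mixed_threshold,
                       min_frac = 0.001) {
  hm <- suppressWarnings(expression_heatmap(model, pooled))
  sc <- hm$scaled
  flagged <- logical(nrow(sc))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    if (!all(c(a, b) %in% colnames(sc))) next
    flagged <- flagged | (sc[, a] > threshold & sc[, b] > threshold)
  }
  meta <- .meta_assignment(model)
  ids_all <- sort(unique(model$node_to_metacluster))
  size_frac <- as.numeric(table(factor(meta, levels = ids_all))) /
    length(meta)
  flagged <- flagged & size_frac >= min_frac
  ids <- ids_all[flagged]
  model$excluded_metaclusters <- as.integer(ids)
  model$heatmap <- hm
  model
}

#' Generate phenotype labels for metaclusters
#'
#' Markers whose scaled median exceeds the threshold are appended with a
#' `+`; metaclusters with no suprathreshold marker are labelled `dim`.
#'
#' @param model a `cluster_model` carrying a heatmap (run [flag_mixed()] or
#'   pass `pooled`).
#' @param pooled optional `pooled_events` to (re)compute the heatmap.
#' @param threshold scaled-median threshold (default 0.5).
#' @return the model with `subset_labels` set.
#' @export
label_subsets <- function(model, pooled = NULL, threshold = 0.5) {
  hm <- model$heatmap %||% expression_heatmap(model, pooled)
  sc <- hm$scaled
  labs <- apply(sc, 1L, function(v) {
    pos <- colnames(sc)[v > threshold]
    if (!length(pos)) "dim" else paste0(paste(pos, collapse = "+"), "+")
  })
  ids <- sort(unique(model$node_to_metacluster))
  model$subset_labels <- setNames(labs, paste0("mc", ids))
  model
}

#' Subset frequency table
#'
#' Per-subject percentage of CD45+ events in each retained metacluster.
#' Excluded metaclusters are dropped from the columns but their events stay
#' in the per-subject denominator, so values are percentages of all of the
#' subject's events (as frequencies of CD45+ PBMC are reported), and the
#' pre-exclusion frequencies sum to 100.
#'
#' @param model a metaclustered `cluster_model`.
#' @param pooled the `pooled_events` the model was fitted to.
#' @return object of class `subset_frequencies`: list with `freq` (subjects
#'   x retained subsets, percent), `group` (named character), and
#'   `all_freq` (pre-exclusion table).
#' @export
compute_frequencies <- function(model, pooled) {
  meta <- .meta_assignment(model)
  subj <- pooled$subject
  ids <- sort(unique(model$node_to_metacluster))
  tab <- table(factor(subj, levels = unique(subj)),
               factor(meta, levels = ids))
  tot <- rowSums(tab)
  if (any(tot == 0)) {
    stop("subject(s) with zero events: ",
         paste(rownames(tab)[tot == 0], collapse = ", "), call. = FALSE)
  }
  freq_all <- 100 * sweep(unclass(tab), 1L, tot, `/`)
  colnames(freq_all) <- paste0("mc", ids)
  retained <- setdiff(ids, model$excluded_metaclusters)
  grp <- setNames(pooled$group[match(rownames(freq_all), pooled$subject)],
                  rownames(freq_all))
  subset_frequencies(freq_all[, paste0("mc", retained), drop = FALSE],
                     group = grp, all_freq = freq_all)
}

#' Construct a subset-frequency table
#'
#' @param freq numeric matrix, subjects x subsets, percentages in [0, 100];
#'   row names are subject ids.
#' @param group named character vector (`"sepsis"`/`"healthy"`) per subject.
#' @param all_freq optional pre-exclusion table whose rows sum to 100.
#' @return object of class `subset_frequencies`.
#' @export
subset_frequencies <- function(freq, group, all_freq = NULL) {
  freq <- as.matrix(freq)
  if (any(freq < -1e-9) || any(freq > 100 + 1e-9)) {
    stop("frequencies must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(rownames(freq))) {
    rownames(freq) <- names(group) %||%
      sprintf("subject_%03d", seq_len(nrow(freq)))
  }
  if (is.null(names(group))) names(group) <- rownames(freq)
  if (!all(rownames(freq) %in% names(group))) {
    stop("group must cover every subject in the frequency table",
         call. = FALSE)
  }
  structure(list(freq = freq, group = group[rownames(freq)],
                 all_freq = all_freq),
            class = "subset_frequencies")
}

#' @export
print.subset_frequencies <- function(x, ...) {
  cat("<subset_frequencies> ", nrow(x$freq), " subjects x ", ncol(x$freq),
      " subsets (", sum(x$group == "sepsis"), " sepsis / ",
      sum(x$group == "healthy"), " healthy)\n", sep = "")
  invisible(x)
}

#' Frequency table directly from simulated compositions
#'
#' Convenience for composition-level studies (differential abundance,
#' networks, classifiers) that do not need the event stage: subset
#' frequencies are the planted compositions on the percent scale.
#'
#' @param scenario a `cohort_scenario`.
#' @param seed integer seed.
#' @param n_sepsis,n_healthy optional overrides of the scenario counts.
#' @return a `subset_frequencies` object.
#' @export
simulate_frequencies <- function(scenario, seed = NULL,
                                 n_sepsis = scenario$n_sepsis,
                                 n_healthy = scenario$n_healthy) {
  fs <- simulate_compositions(scenario, "sepsis", n = n_sepsis,
                              seed = if (is.null(seed)) NULL else
                                derive_seed(seed, "freq_sepsis"))
  fh <- simulate_compositions(scenario, "healthy", n = n_healthy,
                              seed = if (is.null(seed)) NULL else
                                derive_seed(seed, "freq_healthy"))
  freq <- 100 * rbind(fs, fh)
  rownames(freq) <- c(sprintf("sepsis_%03d", seq_len(n_sepsis)),
                      sprintf("healthy_%03d", seq_len(n_healthy)))
  grp <- setNames(c(rep("sepsis", n_sepsis), rep("healthy", n_healthy)),
                  rownames(freq))
  subset_frequencies(freq, grp)
}

#' Clustering stability across reseeded refits
#'
#' Refits the SOM + metaclustering `repeats` times with derived seeds and
#' reports the mean pairwise adjusted Rand index between the per-event
#' metacluster assignments (clustering is run with multiple repeats to
#' check that cluster phenotypes are stable).
#'
#' @param pooled a `pooled_events` object.
#' @param config a [clustering_config()] with `repeats >= 2`.
#' @return list with `mean_ari` and the `ari` matrix.
#' @export
cluster_stability <- function(pooled, config = clustering_config(repeats = 3L)) {
  stopifnot(config$repeats >= 2)
  assignments <- lapply(seq_len(config$repeats), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("stability", r))
    m <- metacluster(fit_som(pooled, cfg))
    .meta_assignment(m)
  })
  k <- length(assignments)
  ari <- matrix(1, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ari[i, j] <- ari[j, i] <-
        mclust::adjustedRandIndex(assignments[[i]], assignments[[j]])
    }
  }
  list(mean_ari = mean(ari[upper.tri(ari)]), ari = ari)
}

#' Write a cluster model to JSON
#'
#' @param model a `cluster_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(
    codebook = apply(model$codebook, 1, as.numeric, simplify = FALSE),
    markers = colnames(model$codebook),
    node_to_metacluster = as.integer(model$node_to_metacluster),
    excluded_metaclusters = model$excluded_metaclusters,
    subset_labels = model$subset_labels,
    grid = c(model$som$grid_rows, model$som$grid_cols)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
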