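# SOM fitting, metaclustering, mixed-cluster exclusion, frequencies and the
# expression heatmap.

test_that("SOM produces the configured grid and degenerate grids collapse", {
  x <- matrix(rnorm(2000), ncol = 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  som <- som_fit(x, 10, 10, seed = 1)
  expect_equal(nrow(som$codebook), 100L)
  som1 <- som_fit(x, 1, 1, seed = 1)
  expect_true(all(som1$assignment == 1L))
  expect_error(som_fit(x[1:50, ], 10, 10, seed = 1), "fewer events")
})

test_that("SOM assignment equals brute-force nearest codebook", {
  set.seed(42)
  x <- matrix(rnorm(500 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  som <- som_fit(x, 2, 2, seed = 7)
  brute <- apply(x, 1, function(v) {
    d <- colSums((t(som$codebook) - v)^2)
    which.min(d)   # which.min takes the lowest index on ties
  })
  expect_identical(som$assignment, as.integer(brute))
})

test_that("metaclustering is a coarsening with the configured count", {
  set.seed(1)
  arch <- three_archetypes()
  em <- simulate_events(c(0.4, 0.3, 0.3), arch, 3000, seed = 1)
  pooled <- concatenate_events(list(asinh_transform(em)))
  cfg <- clustering_config(grid_rows = 4, grid_cols = 4, n_metaclusters = 3,
                           seed = 2)
  model <- metacluster(fit_som(pooled, cfg))
  expect_equal(length(unique(model$node_to_metacluster)), 3L)
  expect_length(model$node_to_metacluster, 16L)
  # coarsening: events of one node never split across metaclusters
  meta <- model$node_to_metacluster[model$node_assignment]
  split_check <- tapply(meta, model$node_assignment,
                        function(v) length(unique(v)))
  expect_true(all(split_check == 1L))
  # with k = 3 on 3 well-separated archetypes, metaclusters correspond 1-1
  # to archetypes (boundary events may individually stray)
  expect_gte(mclust::adjustedRandIndex(meta, pooled$labels), 0.99)
  modal <- vapply(split(pooled$labels, meta),
                  function(v) as.integer(names(which.max(table(v)))),
                  integer(1))
  expect_setequal(modal, 1:3)
  # k equal to the populated node count is the identity on populated nodes
  occ <- sort(unique(model$node_assignment))
  ident <- metacluster(model, n_metaclusters = length(occ))
  expect_equal(length(unique(ident$node_to_metacluster[occ])), length(occ))
  expect_error(metacluster(model, n_metaclusters = 17), "exceeds")
})

test_that("the mixed-cluster rule flags exclusive-lineage co-expression", {
  mk <- c("CD3", "CD4", "CD19", "CD14", "CD56")
  mkrow <- function(v, n) matrix(rep(v, each = n), n,
                                 dimnames = list(NULL, mk))
  # three "metaclusters": pure T (CD3/CD4), pure B (CD19), T-B mixed
  x <- rbind(mkrow(c(4, 4, 0, 0, 0), 100),
             mkrow(c(0, 0, 4, 0, 0), 100),
             mkrow(c(4, 4, 4, 0, 0), 100))
  pooled <- structure(list(exprs = x, subject = rep("s1", 300),
                           group = rep("sepsis", 300), labels = NULL,
                           scale = "asinh5"),
                      class = "pooled_events")
  model <- structure(list(
    node_assignment = rep(1:3, each = 100),
    node_to_metacluster = 1:3,
    config = clustering_config(grid_rows = 2, grid_cols = 2,
                               n_metaclusters = 3)
  ), class = "cluster_model")
  flagged <- flag_mixed(model, pooled)
  expect_identical(flagged$excluded_metaclusters, 3L)   # only the CD3+CD19+
  # a cluster below the size floor is never excluded
  flagged2 <- flag_mixed(model, pooled, min_frac = 0.5)
  expect_length(flagged2$excluded_metaclusters, 0L)
})

test_that("frequencies conserve mass and keep excluded events in the denominator", {
  mk <- c("CD3", "CD19")
  x <- rbind(matrix(c(4, 0), 60, 2, byrow = TRUE),
             matrix(c(0, 4), 40, 2, byrow = TRUE))
  colnames(x) <- mk
  pooled <- structure(list(exprs = x, subject = rep("s1", 100),
                           group = rep("sepsis", 100), labels = NULL,
                           scale = "asinh5"),
                      class = "pooled_events")
  model <- structure(list(
    node_assignment = rep(1:2, c(60, 40)),
    node_to_metacluster = 1:2,
    excluded_metaclusters = integer(0),
    config = clustering_config(2, 2, 2)
  ), class = "cluster_model")
  f <- compute_frequencies(model, pooled)
  expect_equal(unname(f$freq["s1", ]), c(60, 40))
  expect_equal(unname(rowSums(f$all_freq)), 100)
  # excluding metacluster 2 drops the column but keeps the denominator
  model$excluded_metaclusters <- 2L
  f2 <- compute_frequencies(model, pooled)
  expect_equal(colnames(f2$freq), "mc1")
  expect_equal(unname(f2$freq["s1", "mc1"]), 60)
  # one subject with all events in one subset: 100% there, 0 elsewhere
  pooled$subject <- rep("s1", 100)
  model$excluded_metaclusters <- integer(0)
  model$node_assignment <- rep(1L, 100)
  f3 <- compute_frequencies(model, pooled)
  expect_equal(unname(f3$freq["s1", ]), c(100, 0))
})

test_that("a planted two-population composition is recovered within a point", {
  arch <- three_archetypes()[1:2]
  em <- simulate_events(c(0.2, 0.8), arch, 50000, seed = 3)
  pooled <- concatenate_events(list(asinh_transform(em)))
  cfg <- clustering_config(grid_rows = 2, grid_cols = 2, n_metaclusters = 2,
                           seed = 3)
  model <- metacluster(fit_som(pooled, cfg))
  f <- compute_frequencies(model, pooled)
  expect_lt(abs(min(f$freq) - 20), 1)
  expect_lt(abs(max(f$freq) - 80), 1)
})

test_that("heatmap scaling is min-max within marker with degenerate guard", {
  mk <- c("a", "b")
  x <- rbind(matrix(c(1, 5), 50, 2, byrow = TRUE),
             matrix(c(3, 5), 50, 2, byrow = TRUE))
  colnames(x) <- mk
  pooled <- structure(list(exprs = x, subject = rep("s1", 100),
                           group = rep("sepsis", 100), labels = NULL,
                           scale = "asinh5"),
                      class = "pooled_events")
  model <- structure(list(
    node_assignment = rep(1:2, each = 50),
    node_to_metacluster = 1:2,
    config = clustering_config(2, 2, 2)
  ), class = "cluster_model")
  expect_warning(hm <- expression_heatmap(model, pooled), "constant")
  expect_equal(unname(hm$scaled[, "a"]), c(0, 1))   # medians 1 and 3
  expect_equal(unname(hm$scaled[, "b"]), c(0, 0))   # constant marker
})

test_that("the full clustering chain reproduces the subset bookkeeping", {
  fx <- clustered_fixture()
  expect_equal(nrow(fx$model$codebook), 100L)
  expect_equal(length(unique(fx$model$node_to_metacluster)), 47L)
  expect_length(fx$model$excluded_metaclusters, 1L)
  expect_equal(ncol(fx$freqs$freq), 46L)
  expect_equal(unname(rowSums(fx$freqs$all_freq)),
               rep(100, 58), tolerance = 1e-6)
  # node purity against the generator truth
  purity <- sum(vapply(split(fx$pooled$labels, fx$model$node_assignment),
                       function(v) max(table(v)), numeric(1))) /
    length(fx$pooled$labels)
  expect_gte(purity, 0.9)
  # the excluded metacluster is the planted doublet population
  meta <- fx$model$node_to_metacluster[fx$model$node_assignment]
  in_excl <- meta %in% fx$model$excluded_metaclusters
  expect_equal(as.integer(names(which.max(table(fx$pooled$labels[in_excl])))),
               20L)
  # the planted CD15+CD14+ monocyte archetype scores at the top of both of
  # its defining markers (the classical monocyte shares the CD14 apex)
  hm <- fx$model$heatmap
  mono_mc <- names(which.max(table(
    meta[fx$pooled$labels == 1])))   # archetype 1 = CD15+CD14+ monocyte
  expect_gte(unname(hm$scaled[paste0("mc", mono_mc), "CD14"]), 0.9)
  expect_gte(unname(hm$scaled[paste0("mc", mono_mc), "CD15"]), 0.9)
  # subset labels mark the monocyte metacluster CD14-positive
  lab_model <- label_subsets(fx$model)
  expect_match(lab_model$subset_labels[paste0("mc", mono_mc)], "CD14")
})

test_that("reseeded refits give stable metacluster assignments", {
  fx <- clustered_fixture()
  # moderate subsample to keep the repeated fits cheap
  idx <- seq(1, nrow(fx$pooled$exprs), by = 3)
  sub <- fx$pooled
  sub$exprs <- sub$exprs[idx, , drop = FALSE]
  sub$subject <- sub$subject[idx]
  sub$group <- sub$group[idx]
  sub$labels <- sub$labels[idx]
  st <- cluster_stability(sub, clustering_config(repeats = 3L, seed = 5))
  expect_gte(st$mean_ari, 0.8)
})
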