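# End-to-end orchestration: simulate -> preprocess -> cluster -> embed ->
# diffabund -> network -> classify -> report, with a single master seed,
# per-stage derived seeds, structured logging and a provenance manifest.

.PIPELINE_STAGES <- c("simulate", "preprocess", "cluster", "embed",
                      "diffabund", "network", "classify", "report")

#' Build a pipeline run configuration
#'
#' One master seed drives every stochastic stage through deterministically
#' derived child seeds, so a single integer reproduces an entire run.
#'
#' @param seed master seed.
#' @param out_dir run directory.
#' @param scenario a `cohort_scenario` (default: the discovery scenario).
#' @param events_per_subject events simulated per subject.
#' @param downsample_to per-subject downsampling target for clustering.
#' @param cofactor asinh cofactor.
#' @param clustering a [clustering_config()].
#' @param embed_events events sampled for the 2-D embedding stage.
#' @param perplexity t-SNE perplexity.
#' @param network_threshold,network_alpha edge rule for the networks.
#' @param alpha differential-abundance adjusted-p threshold.
#' @param stages named logical vector toggling stages (order is fixed).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("immunome_run_"),
                       scenario = NULL,
                       events_per_subject = NULL,
                       downsample_to = 50000L,
                       cofactor = 5,
                       clustering = clustering_config(),
                       embed_events = 2000L,
                       perplexity = 30,
                       network_threshold = 0.6,
                       network_alpha = 0.05,
                       alpha = 0.1,
                       stages = setNames(rep(TRUE, length(.PIPELINE_STAGES)),
                                         .PIPELINE_STAGES)) {
  st <- setNames(rep(TRUE, length(.PIPELINE_STAGES)), .PIPELINE_STAGES)
  st[names(stages)] <- stages
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, scenario = scenario,
         events_per_subject = events_per_subject,
         downsample_to = as.integer(downsample_to), cofactor = cofactor,
         clustering = clustering, embed_events = as.integer(embed_events),
         perplexity = perplexity, network_threshold = network_threshold,
         network_alpha = network_alpha, alpha = alpha, stages = st),
    class = "run_config"
  )
}

.log_stage <- function(con, stage, seed, t0) {
  line <- sprintf("[%s] stage=%s seed=%d wall=%.2fs",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0)
  writeLines(line, con)
  message(line)
}

# hash of the configuration: serialise to canonical JSON, md5 the bytes
.config_hash <- function(config) {
  ser <- list(seed = config$seed,
              scenario = config$scenario$name %||% "default",
              events_per_subject = config$events_per_subject,
              downsample_to = config$downsample_to,
              cofactor = config$cofactor,
              grid = c(config$clustering$grid_rows,
                       config$clustering$grid_cols),
              n_metaclusters = config$clustering$n_metaclusters,
              embed_events = config$embed_events,
              perplexity = config$perplexity,
              network = c(config$network_threshold, config$network_alpha),
              alpha = config$alpha,
              stages = as.list(config$stages))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order, writing each stage's
#' artifacts under `out_dir` and a provenance manifest
#' (`manifest.json`: configuration hash, per-stage seeds and output
#' checksums).  Reruns with the same configuration are bit-identical for the
#' deterministic stages.  A stage failure halts the run with a stage-named
#' error; artifacts of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "at")
  on.exit(close(log_con))
  scenario <- config$scenario %||% build_default_scenario()
  events_n <- config$events_per_subject %||% scenario$events_per_subject
  res <- list()
  manifest <- list(config_hash = .config_hash(config),
                   master_seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("sepsisimmune")),
                   stages = list())
  outputs <- character(0)

  run_stage <- function(stage, fn) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    seed <- derive_seed(config$seed, stage)
    t0 <- as.numeric(Sys.time())
    before <- outputs
    result <- tryCatch(fn(seed), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    new_files <- setdiff(outputs, before)
    manifest$stages[[stage]] <<- list(
      seed = seed,
      outputs = as.list(setNames(as.character(tools::md5sum(new_files)),
                                 basename(new_files)))
    )
    .log_stage(log_con, stage, seed, t0)
    result
  }
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  # simulate ---------------------------------------------------------------
  res$cohort <- run_stage("simulate", function(seed) {
    sim_dir <- file.path(config$out_dir, "cohort")
    g <- generate_cohort(scenario, sim_dir, seed = seed,
                         events_per_subject = events_n)
    for (f in c(g$event_files, g$clinical_file, g$truth_file)) emit(f)
    g
  })

  # preprocess -------------------------------------------------------------
  res$pooled <- run_stage("preprocess", function(seed) {
    cohort <- read_cohort(file.path(config$out_dir, "cohort"))
    mats <- lapply(seq_along(cohort$events), function(i) {
      em <- asinh_transform(cohort$events[[i]], config$cofactor)
      downsample_events(em, min(config$downsample_to, events_n),
                        seed = derive_seed(seed, paste0("ds", i)))
    })
    pooled <- concatenate_events(mats)
    path <- file.path(config$out_dir, "pooled_summary.tsv")
    write.table(data.frame(subject = unique(pooled$subject),
                           events = as.integer(table(pooled$subject)[
                             unique(pooled$subject)])),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(path)
    pooled
  })

  # cluster ----------------------------------------------------------------
  res$freqs <- run_stage("cluster", function(seed) {
    cfg <- config$clustering
    cfg$seed <- seed
    model <- fit_som(res$pooled, cfg)
    model <- metacluster(model)
    model <- flag_mixed(model, res$pooled)
    model <- label_subsets(model)
    freqs <- compute_frequencies(model, res$pooled)
    res$model <<- model
    fp <- file.path(config$out_dir, "subset_frequencies.tsv")
    write.table(data.frame(subject_id = rownames(freqs$freq),
                           group = freqs$group, freqs$freq,
                           check.names = FALSE),
                fp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(fp)
    hp <- file.path(config$out_dir, "heatmap_scaled.tsv")
    write.table(model$heatmap$scaled, hp, sep = "\t", quote = FALSE)
    emit(hp)
    emit(write_cluster_model(model,
                             file.path(config$out_dir, "cluster_model.json")))
    freqs
  })

  # embed ------------------------------------------------------------------
  res$embedding <- run_stage("embed", function(seed) {
    pca <- subject_pca(res$freqs)
    sp <- file.path(config$out_dir, "pca_scores.tsv")
    write.table(pca$scores, sp, sep = "\t", quote = FALSE)
    emit(sp)
    lp <- file.path(config$out_dir, "pca_loadings.tsv")
    write.table(pca$loadings, lp, sep = "\t", quote = FALSE)
    emit(lp)
    n_embed <- min(config$embed_events, nrow(res$pooled$exprs))
    idx <- with_seed_opt(derive_seed(seed, "embed_sample"),
                         sort(sample.int(nrow(res$pooled$exprs), n_embed)))
    emb <- event_embedding(res$pooled$exprs[idx, , drop = FALSE],
                           perplexity = min(config$perplexity,
                                            (n_embed - 1) %/% 4),
                           seed = derive_seed(seed, "tsne"))
    cp <- file.path(config$out_dir, "tsne_coordinates.tsv")
    write.table(data.frame(event = idx, emb$coordinates), cp, sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(cp)
    list(pca = pca, tsne = emb, tsne_rows = idx)
  })

  # diffabund --------------------------------------------------------------
  res$differential <- run_stage("diffabund", function(seed) {
    da <- test_subsets(res$freqs, alpha = config$alpha)
    dp <- file.path(config$out_dir, "differential_abundance.tsv")
    write.table(da, dp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(dp)
    da
  })

  # network ----------------------------------------------------------------
  res$networks <- run_stage("network", function(seed) {
    nets <- lapply(c(healthy = "healthy", sepsis = "sepsis"), function(g) {
      build_network(group_correlations(res$freqs, g),
                    threshold = config$network_threshold,
                    alpha_edge = config$network_alpha, group = g)
    })
    contrast <- compare_networks(nets$healthy, nets$sepsis)
    for (g in names(nets)) {
      emit(write_edge_list(nets[[g]],
                           file.path(config$out_dir,
                                     paste0("network_", g, ".tsv"))))
      emit(write_network_graphml(nets[[g]],
                                 file.path(config$out_dir,
                                           paste0("network_", g,
                                                  ".graphml"))))
      lay <- layout_network(nets[[g]], seed = derive_seed(seed, g))
      lp <- file.path(config$out_dir, paste0("layout_", g, ".tsv"))
      write.table(lay, lp, sep = "\t", quote = FALSE)
      emit(lp)
    }
    sp <- file.path(config$out_dir, "network_summary.json")
    jsonlite::write_json(
      lapply(list(healthy = contrast$healthy, sepsis = contrast$sepsis),
             function(s) unclass(s)[c("n", "E", "density", "negative_edges",
                                      "negative_fraction", "modularity",
                                      "isolated")]),
      sp, auto_unbox = TRUE, digits = NA)
    emit(sp)
    c(nets, list(contrast = contrast))
  })

  # classify ---------------------------------------------------------------
  res$classifier <- run_stage("classify", function(seed) {
    clinical <- res$cohort$clinical
    # diagnostic model on the enriched subsets as labelled by the pipeline:
    # pick the retained subsets with the largest positive effect sizes
    da <- res$differential
    up <- da$subset[order(-da$d)][1:min(4, nrow(da))]
    fit4 <- fit_subset_model(model_spec(up, "sepsis"), res$freqs, clinical)
    metrics <- roc_metrics(fit4$scores, fit4$labels)
    mp <- file.path(config$out_dir, "classifier_metrics.json")
    jsonlite::write_json(
      metrics[c("auc", "auc_lower", "auc_upper", "cutoff", "sensitivity",
                "specificity", "ppv", "npv", "n_cases", "n_controls")],
      mp, auto_unbox = TRUE, digits = NA)
    emit(mp)
    rp <- file.path(config$out_dir, "roc_curve.tsv")
    write.table(metrics$curve, rp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(rp)
    list(model = fit4, metrics = metrics, predictors = up)
  })

  # report -----------------------------------------------------------------
  res$report <- run_stage("report", function(seed) {
    clinical <- res$cohort$clinical
    summ <- cohort_summary(clinical)
    sp <- file.path(config$out_dir, "cohort_summary.tsv")
    write.table(summ, sp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(sp)
    summ
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
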