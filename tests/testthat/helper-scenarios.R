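# Shared scenario fixtures, built in code.  The default scenario is cached
# once per test run (its Monte-Carlo calibration is deterministic).

default_scenario <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) sc <<- build_default_scenario()
    sc
  }
})

# a true null: no group shift, identical covariance in both groups
null_scenario <- function() {
  sc <- default_scenario()
  sc$group_shift[] <- 0
  sc$covariance_sepsis <- sc$covariance_healthy
  sc
}

# planted correlation blocks (|rho| = 0.8) for edge-recovery checks; the
# truth adjacency is |R| > 0.6 off the diagonal
block_scenario <- function(sigma_log = 0.35) {
  sc <- default_scenario()
  k <- length(sc$subsets)
  r <- diag(k)
  r[2:5, 2:5] <- 0.8
  r[8:10, 8:10] <- 0.8
  r[13, 14] <- r[14, 13] <- -0.8
  diag(r) <- 1
  dimnames(r) <- list(sc$subsets, sc$subsets)
  sc$covariance_healthy <- sigma_log^2 * r
  sc$covariance_sepsis <- sc$covariance_healthy
  validate_scenario(sc)
  list(scenario = sc, truth_r = r)
}

# degenerate scenario: zero covariance and zero shift
degenerate_scenario <- function() {
  sc <- default_scenario()
  k <- length(sc$subsets)
  sc$group_shift[] <- 0
  zero <- matrix(0, k, k, dimnames = dimnames(sc$covariance_healthy))
  sc$covariance_healthy <- zero
  sc$covariance_sepsis <- zero
  sc
}

# three well-separated archetypes for small clustering tests
three_archetypes <- function() {
  arch <- default_archetypes()
  names(arch) <- vapply(arch, `[[`, character(1), "name")
  arch[c("Naive CD4", "Naive B", "Classical monocyte")]
}

# small clustered cohort shared by the event-level tests: 58 subjects,
# `events` events each, asinh5-transformed and pooled
clustered_fixture <- local({
  cache <- NULL
  function(events = 1200L, seed = 1L) {
    key <- paste(events, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    sc <- build_default_scenario(events_per_subject = events, seed = seed)
    dir <- file.path(tempdir(), paste0("cohort_fixture_", events, "_", seed))
    gen <- generate_cohort(sc, dir, seed = seed)
    cohort <- read_cohort(dir)
    pooled <- concatenate_events(lapply(cohort$events, asinh_transform))
    model <- fit_som(pooled, clustering_config(seed = seed))
    model <- metacluster(model)
    model <- flag_mixed(model, pooled)
    value <- list(scenario = sc, gen = gen, cohort = cohort,
                  pooled = pooled, model = model,
                  freqs = compute_frequencies(model, pooled))
    cache <<- list(key = key, value = value)
    value
  }
})
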