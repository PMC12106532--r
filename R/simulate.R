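# Cohort simulation: subject compositions, event-level intensities, clinical
# records, and on-disk cohort generation.

#' Simulate subject-level subset compositions
#'
#' Draws per-subject log-abundance vectors from the group mean (baseline plus
#' the sepsis shift) and the group's log-scale covariance, then maps through
#' the softmax closure to compositions summing to one (a logistic-normal
#' model, which supports planted positive and negative covariance between
#' subset frequencies).
#'
#' @param scenario a `cohort_scenario`.
#' @param group `"sepsis"` or `"healthy"`.
#' @param n number of subjects (defaults to the scenario's count for the
#'   group).
#' @param seed optional integer seed.
#' @return matrix `n` x subsets of compositions; rows sum to 1.
#' @export
#' @examples
#' sc <- build_default_scenario()
#' comp <- simulate_compositions(sc, "healthy", n = 5, seed = 1)
#' rowSums(comp)
simulate_compositions <- function(scenario, group = c("sepsis", "healthy"),
                                  n = NULL, seed = NULL) {
  group <- match.arg(group)
  mu <- scenario$base_logratio_mean
  if (group == "sepsis") mu <- mu + scenario$group_shift
  sigma <- if (group == "sepsis") scenario$covariance_sepsis else
    scenario$covariance_healthy
  assert_psd(sigma, paste0("covariance_", group))
  n <- n %||% if (group == "sepsis") scenario$n_sepsis else scenario$n_healthy
  eta <- with_seed_opt(seed, MASS::mvrnorm(n, mu, sigma))
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, scenario$subsets))
  close_compositions(eta)
}

#' Simulate single-cell events for one subject
#'
#' Each event is assigned a population by a multinomial draw with the
#' subject's composition weights, then raw marker intensities are drawn from
#' that population archetype's zero-inflated lognormal model.  True
#' population labels are kept on the returned matrix for recovery testing.
#'
#' @param composition numeric composition vector (one weight per archetype,
#'   summing to 1).
#' @param archetypes list of `population_archetype`.
#' @param events_per_subject number of events to draw.
#' @param seed optional integer seed.
#' @param subject_id,group provenance for the returned `event_matrix`.
#' @return a raw-scale `event_matrix` with `labels` set to archetype indices.
#' @export
simulate_events <- function(composition, archetypes, events_per_subject,
                            seed = NULL, subject_id = "subject",
                            group = NA_character_) {
  if (length(archetypes) == 0L) stop("empty archetype list", call. = FALSE)
  stopifnot(length(composition) == length(archetypes),
            events_per_subject >= 1)
  markers <- names(archetypes[[1]]$mean_raw)
  n <- as.integer(events_per_subject)
  with_seed_opt(seed, {
    lab <- sample.int(length(archetypes), n, replace = TRUE,
                      prob = composition)
    x <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    for (a in seq_along(archetypes)) {
      rows <- which(lab == a)
      if (!length(rows)) next
      arc <- archetypes[[a]]
      na <- length(rows)
      vals <- matrix(
        rlnorm(na * length(markers),
               meanlog = rep(log(arc$mean_raw), each = na),
               sdlog = rep(arc$sdlog, each = na)),
        nrow = na
      )
      nz <- matrix(
        runif(na * length(markers)) >= rep(arc$p_zero, each = na),
        nrow = na
      )
      x[rows, ] <- vals * nz
    }
    event_matrix(x, subject_id = subject_id, group = group,
                 scale = "raw", labels = lab)
  })
}

.SITE_LEVELS <- c("respiratory", "systemic", "gastrointestinal",
                  "central nervous system", "musculoskeletal",
                  "genitourinary")
.SITE_PROBS <- c(0.712, 0.085, 0.119, 0.034, 0.034, 0.017)

.draw_ages <- function(n, model, probs) {
  br <- model$breaks
  bracket <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  runif(n, br[bracket], br[bracket + 1L])
}

#' Simulate clinical records coupled to subset frequencies
#'
#' Laboratory values for sepsis subjects are linear in the (standardised)
#' frequency of their coupled subset with Gaussian noise calibrated so the
#' population Pearson correlation equals the coupling target; outcomes are
#' Bernoulli draws from the scenario's logistic link on subset frequencies;
#' severity scores are discretised Gaussians sharing a latent severity axis
#' with the outcome linear predictor (only their rank structure is used
#' downstream).  Healthy subjects carry no severity scores, laboratory
#' values, or infection site, and all outcome flags are `FALSE`; every
#' sepsis subject's pSOFA is at least 2 (the organ-dysfunction rise that
#' defines sepsis).
#'
#' @param compositions matrix from [simulate_compositions()].
#' @param group `"sepsis"` or `"healthy"`.
#' @param scenario a `cohort_scenario`.
#' @param seed optional integer seed.
#' @param subject_ids optional character vector of ids.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `age_years`, `psofa`, `pelod2`, `pim3`, `crp`, `procalcitonin`,
#'   `lactate`, `wbc`, `site_of_infection`, `severe_sepsis`, `septic_shock`,
#'   `multiorgan_dysfunction`, `picu_mortality`.
#' @export
simulate_clinical <- function(compositions, group = c("sepsis", "healthy"),
                              scenario, seed = NULL, subject_ids = NULL) {
  group <- match.arg(group)
  n <- nrow(compositions)
  freq <- 100 * compositions
  ids <- subject_ids %||% sprintf("%s_%03d", group, seq_len(n))
  couplings <- scenario$clinical_couplings
  if (!is.null(couplings) && any(abs(couplings$r) >= 1)) {
    stop("clinical coupling target |r| must be < 1", call. = FALSE)
  }
  with_seed_opt(seed, {
    rec <- data.frame(
      subject_id = ids,
      group = group,
      age_years = .draw_ages(n, scenario$age_model,
                             scenario$age_model[[group]]),
      psofa = NA_real_, pelod2 = NA_real_, pim3 = NA_real_,
      crp = NA_real_, procalcitonin = NA_real_, lactate = NA_real_,
      wbc = NA_real_,
      site_of_infection = NA_character_,
      severe_sepsis = FALSE, septic_shock = FALSE,
      multiorgan_dysfunction = FALSE, picu_mortality = FALSE,
      stringsAsFactors = FALSE
    )
    if (group == "healthy") return(rec)

    fm <- scenario$freq_moments$sepsis
    zf <- scale(freq, center = fm$mean[colnames(freq)],
                scale = fm$sd[colnames(freq)])

    coupled_vars <- if (is.null(couplings)) character(0) else
      couplings$variable
    for (v in names(scenario$lab_models)) {
      lm <- scenario$lab_models[[v]]
      if (v %in% coupled_vars) {
        cp <- couplings[couplings$variable == v, , drop = FALSE][1, ]
        z <- cp$r * zf[, cp$subset] +
          sqrt(1 - cp$r^2) * rnorm(n)
      } else {
        z <- rnorm(n)
      }
      rec[[v]] <- pmax(lm$mean + lm$sd * z, lm$min)
    }

    om <- scenario$outcome_model
    zo <- zf[, om$predictors, drop = FALSE]
    lin_mort <- drop(zo %*% om$coef$picu_mortality)
    for (o in names(om$coef)) {
      p <- plogis(om$intercepts[[o]] + drop(zo %*% om$coef[[o]]))
      rec[[o]] <- runif(n) < p
    }

    rho <- om$latent_rho
    zl <- lin_mort / max(om$lin_sd[["picu_mortality"]], 1e-8)
    sev_z <- function() rho * zl + sqrt(1 - rho^2) * rnorm(n)
    rec$psofa <- pmin(pmax(round(8 + 3.2 * sev_z()), 2), 16)
    rec$pelod2 <- pmin(pmax(round(5.8 + 3.0 * sev_z()), 0), 20)
    rec$pim3 <- pmin(pmax(exp(log(3.4) + 0.8 * sev_z()), 0.05), 60)
    rec$site_of_infection <- sample(.SITE_LEVELS, n, replace = TRUE,
                                    prob = .SITE_PROBS)
    rec
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one TSV event file per subject (markers plus a true-population
#' column), a clinical table (`clinical.tsv`), and a truth sidecar
#' (`truth.json`) holding the planted compositions, shifts, covariances and
#' couplings for recovery tests.  Fully reproducible from the seed: the same
#' seed yields byte-identical outputs.
#'
#' @param scenario a `cohort_scenario`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed (defaults to `scenario$seed`).
#' @param events_per_subject override of the scenario's event count.
#' @return invisibly, a list with `event_files`, `clinical_file`,
#'   `truth_file`, `clinical` (the data.frame) and `compositions`.
#' @export
generate_cohort <- function(scenario, out_dir,
                            seed = scenario$seed,
                            events_per_subject = scenario$events_per_subject) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  groups <- c(rep("sepsis", scenario$n_sepsis),
              rep("healthy", scenario$n_healthy))
  comp <- list(
    sepsis = simulate_compositions(scenario, "sepsis",
                                   seed = derive_seed(seed, "comp_sepsis")),
    healthy = simulate_compositions(scenario, "healthy",
                                    seed = derive_seed(seed, "comp_healthy"))
  )
  clin <- rbind(
    simulate_clinical(comp$sepsis, "sepsis", scenario,
                      seed = derive_seed(seed, "clin_sepsis"),
                      subject_ids = sprintf("sepsis_%03d",
                                            seq_len(scenario$n_sepsis))),
    simulate_clinical(comp$healthy, "healthy", scenario,
                      seed = derive_seed(seed, "clin_healthy"),
                      subject_ids = sprintf("healthy_%03d",
                                            seq_len(scenario$n_healthy)))
  )
  all_comp <- rbind(comp$sepsis, comp$healthy)
  event_files <- character(nrow(clin))
  for (i in seq_len(nrow(clin))) {
    em <- simulate_events(all_comp[i, ], scenario$archetypes,
                          events_per_subject,
                          seed = derive_seed(seed,
                                             paste0("events_",
                                                    clin$subject_id[i])),
                          subject_id = clin$subject_id[i],
                          group = clin$group[i])
    event_files[i] <- file.path(out_dir,
                                paste0(clin$subject_id[i], ".tsv"))
    write_event_tsv(em, event_files[i])
  }
  clinical_file <- file.path(out_dir, "clinical.tsv")
  write.table(clin, clinical_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(
    scenario = scenario$name,
    seed = as.integer(seed),
    subsets = scenario$subsets,
    subject_id = clin$subject_id,
    group = clin$group,
    compositions = unname(apply(all_comp, 1, as.numeric, simplify = FALSE)),
    base_logratio_mean = as.numeric(scenario$base_logratio_mean),
    group_shift = as.numeric(scenario$group_shift),
    target_d = as.numeric(scenario$target_d %||% rep(0, length(scenario$subsets))),
    covariance_healthy = apply(scenario$covariance_healthy, 1, as.numeric,
                               simplify = FALSE),
    covariance_sepsis = apply(scenario$covariance_sepsis, 1, as.numeric,
                              simplify = FALSE),
    clinical_couplings = scenario$clinical_couplings
  )
  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(event_files = event_files, clinical_file = clinical_file,
                 truth_file = truth_file, clinical = clin,
                 compositions = all_comp))
}

#' Read a generated cohort from disk
#'
#' @param dir directory written by [generate_cohort()].
#' @return list with `events` (list of raw-scale `event_matrix`), `clinical`
#'   (data.frame), and `truth` (parsed sidecar, or `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  clinical <- read.table(file.path(dir, "clinical.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  events <- lapply(seq_len(nrow(clinical)), function(i) {
    read_event_tsv(file.path(dir, paste0(clinical$subject_id[i], ".tsv")),
                   subject_id = clinical$subject_id[i],
                   group = clinical$group[i])
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(events = events, clinical = clinical, truth = truth)
}
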