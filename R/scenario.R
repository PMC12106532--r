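# Cohort scenarios: the statistical structure the generator plants and the
# downstream analysis is expected to recover.

.CALIBRATION_SEED <- 20250913L
.CALIBRATION_N <- 20000L

#' Softmax closure of log-abundance vectors
#' @param eta matrix (subjects x subsets) of log-abundances.
#' @return matrix of compositions, rows summing to 1.
#' @keywords internal
close_compositions <- function(eta) {
  m <- apply(eta, 1L, max)
  w <- exp(eta - m)
  w / rowSums(w)
}

# Factor-model correlation matrix: R = L L' + diag(1 - rowSums(L^2)).
# Guaranteed PSD for |rowSums(L^2)| <= 1.
.factor_corr <- function(loadings) {
  cm <- tcrossprod(loadings)
  diag(cm) <- 1
  cm
}

#' Construct a cohort scenario
#'
#' Low-level constructor; most users want [build_default_scenario()].  A
#' scenario bundles the composition model (baseline log-abundances, sepsis
#' shift, per-group log-scale covariance), the event-level archetypes, the
#' clinical coupling targets and outcome model, and the subject counts.
#'
#' @param name scenario label.
#' @param n_sepsis,n_healthy subject counts.
#' @param archetypes list of `population_archetype` (see
#'   [default_archetypes()]).
#' @param base_logratio_mean named baseline log-abundance vector (one entry
#'   per archetype).
#' @param group_shift named additive log-abundance shift applied to sepsis
#'   subjects.
#' @param covariance_healthy,covariance_sepsis log-scale covariance matrices.
#' @param target_d named planted standardised effect sizes (frequency scale);
#'   zero entries mean no planted shift.
#' @param clinical_couplings data.frame with columns `subset`, `variable`,
#'   `r` (target Pearson correlation, `|r| < 1`).
#' @param lab_models named list of `list(mean, sd, min)` per laboratory
#'   variable on its reporting scale.
#' @param outcome_model list with `predictors` (subset names), per-outcome
#'   coefficient vectors and calibrated intercepts (see
#'   [build_default_scenario()]).
#' @param age_model list with per-group age-bracket probabilities.
#' @param freq_moments per-group list of subset-frequency means/sds (percent
#'   scale) used to standardise frequencies in the clinical couplings.
#' @param events_per_subject events drawn per subject by [simulate_events()].
#' @param panel a `marker_panel`.
#' @param seed scenario seed.
#' @param separation_margin minimum nearest-centroid distance between
#'   archetypes after the asinh transform.
#' @return an object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(name, n_sepsis, n_healthy, archetypes,
                            base_logratio_mean, group_shift,
                            covariance_healthy, covariance_sepsis,
                            target_d = NULL, clinical_couplings = NULL,
                            lab_models = NULL, outcome_model = NULL,
                            age_model = NULL, freq_moments = NULL,
                            events_per_subject = 60000L,
                            panel = default_marker_panel(),
                            seed = 1L, separation_margin = 1.5) {
  subsets <- vapply(archetypes, `[[`, character(1), "name")
  stopifnot(
    length(base_logratio_mean) == length(subsets),
    length(group_shift) == length(subsets),
    n_sepsis >= 1, n_healthy >= 1, events_per_subject >= 1
  )
  names(base_logratio_mean) <- subsets
  names(group_shift) <- subsets
  sc <- structure(
    list(
      name = name,
      n_sepsis = as.integer(n_sepsis),
      n_healthy = as.integer(n_healthy),
      panel = panel,
      archetypes = archetypes,
      subsets = subsets,
      base_logratio_mean = base_logratio_mean,
      group_shift = group_shift,
      covariance_healthy = covariance_healthy,
      covariance_sepsis = covariance_sepsis,
      target_d = target_d,
      clinical_couplings = clinical_couplings,
      lab_models = lab_models,
      outcome_model = outcome_model,
      age_model = age_model,
      freq_moments = freq_moments,
      events_per_subject = as.integer(events_per_subject),
      seed = as.integer(seed),
      separation_margin = separation_margin
    ),
    class = "cohort_scenario"
  )
  validate_scenario(sc)
  sc
}

#' Validate a cohort scenario
#'
#' Checks the invariants a scenario must satisfy: symmetric PSD covariance
#' matrices, coupling targets inside (-1, 1), archetype centroids pairwise
#' separated beyond the configured margin on the asinh scale, and (when
#' planted effects are declared) the enriched/depleted bookkeeping.
#'
#' @param scenario a `cohort_scenario`.
#' @return the scenario, invisibly; errors on violation.
#' @export
validate_scenario <- function(scenario) {
  assert_psd(scenario$covariance_healthy, "covariance_healthy")
  assert_psd(scenario$covariance_sepsis, "covariance_sepsis")
  if (!is.null(scenario$clinical_couplings)) {
    if (any(abs(scenario$clinical_couplings$r) >= 1)) {
      stop("clinical coupling target |r| must be < 1", call. = FALSE)
    }
    miss <- setdiff(scenario$clinical_couplings$subset, scenario$subsets)
    if (length(miss)) stop("coupling subset not in scenario: ", miss[1])
  }
  cent <- vapply(scenario$archetypes, archetype_centroid,
                 numeric(length(scenario$panel$markers)))
  dmat <- as.matrix(dist(t(cent)))
  diag(dmat) <- Inf
  if (min(dmat) <= scenario$separation_margin) {
    stop("archetypes not separable: nearest-centroid distance ",
         signif(min(dmat), 3), " <= margin ", scenario$separation_margin,
         call. = FALSE)
  }
  invisible(scenario)
}

# Monte-Carlo calibration of log-scale shifts so that the planted effect
# sizes hold on the observed frequency (percent) scale, where the analysis
# measures them.  The softmax closure attenuates log-scale shifts in a
# composition-dependent way, so a fixed-seed iterative rescaling is used.
.calibrate_shifts <- function(mu, delta, sig_h, sig_s, target_d,
                              w = c(38, 18), iters = 4L) {
  idx <- which(target_d != 0)
  for (it in seq_len(iters)) {
    f_h <- with_seed_opt(.CALIBRATION_SEED + it, {
      100 * close_compositions(MASS::mvrnorm(.CALIBRATION_N, mu, sig_h))
    })
    f_s <- with_seed_opt(.CALIBRATION_SEED + 100L + it, {
      100 * close_compositions(MASS::mvrnorm(.CALIBRATION_N, mu + delta,
                                             sig_s))
    })
    pooled_sd <- sqrt((w[1] * apply(f_s, 2, var) +
                       w[2] * apply(f_h, 2, var)) / sum(w))
    d_hat <- (colMeans(f_s) - colMeans(f_h)) / pooled_sd
    ratio <- target_d[idx] / d_hat[idx]
    ratio[!is.finite(ratio) | ratio <= 0] <- 1
    delta[idx] <- delta[idx] * pmin(pmax(ratio, 0.5), 2)
  }
  list(delta = delta,
       freq_moments = list(
         healthy = list(mean = colMeans(f_h), sd = apply(f_h, 2, sd)),
         sepsis = list(mean = colMeans(f_s), sd = apply(f_s, 2, sd))
       ))
}

# Calibrate a logistic-link intercept so the marginal outcome prevalence over
# a Monte-Carlo draw of linear predictors matches `target`.
.calibrate_intercept <- function(lin, target) {
  uniroot(function(a) mean(plogis(a + lin)) - target,
          lower = -30, upper = 30, tol = 1e-8)$root
}

#' Build the default cohort scenario
#'
#' The default scenario emulates the statistical structure of a paediatric
#' sepsis discovery study: 39 sepsis and 19 healthy subjects (20 and 15 for
#' the validation variant), twenty cell-population archetypes of which four
#' are enriched and seven depleted in sepsis, dense cross-lineage inter-subset
#' correlations with negative edges in health versus sparse, modular,
#' all-positive correlations in sepsis, and clinical couplings
#' (CD15+CD14+ monocytes with procalcitonin at Pearson r 0.68; memory Th17
#' cells with lactate at r 0.57).  Planted effect sizes are standardised
#' (Cohen's d on the frequency scale): 1.5 for the monocyte subset (the
#' largest), 1.2 for the Th17 subset, 1.4 and 1.3 for the remaining enriched
#' subsets, and -0.8 to -1.2 for the depleted ones; shifts are calibrated by
#' fixed-seed Monte Carlo so the targets hold after the compositional
#' closure.  Outcome prevalences among sepsis subjects are calibrated to
#' severe sepsis 74.6%, septic shock 72.9%, multiorgan dysfunction 69.5% and
#' PICU mortality 13.6%.
#'
#' @param cohort `"discovery"` (39 + 19) or `"validation"` (20 + 15).
#' @param events_per_subject events per subject for event-level simulation.
#' @param seed scenario seed (drives [generate_cohort()]).
#' @param sigma_log log-scale subset standard deviation (default 0.35).
#' @return a `cohort_scenario`.
#' @export
#' @examples
#' sc <- build_default_scenario()
#' sc$n_sepsis; sc$n_healthy
#' sum(sc$group_shift > 0); sum(sc$group_shift < 0)
build_default_scenario <- function(cohort = c("discovery", "validation"),
                                   events_per_subject = 60000L,
                                   seed = 1L, sigma_log = 0.35) {
  cohort <- match.arg(cohort)
  panel <- default_marker_panel()
  arch <- default_archetypes(panel)
  subsets <- vapply(arch, `[[`, character(1), "name")
  k <- length(subsets)

  base_pct <- c(2.5, 1.2, 1.5, 1.0,            # enriched
                2.5, 2.0, 3.5, 4.0, 2.0, 4.0, 3.5,  # depleted
                16, 11, 8, 10, 12, 8, 4, 3, 1.5)    # fillers (last = doublet)
  names(base_pct) <- subsets
  mu <- log(base_pct / sum(base_pct))

  target_d <- setNames(rep(0, k), subsets)
  target_d[subsets[1:4]] <- c(1.5, 1.2, 1.4, 1.3)
  target_d[subsets[5:11]] <- c(-1.2, -1.1, -1.0, -1.0, -0.9, -0.9, -0.8)

  # healthy: one cross-lineage communication web (positive loadings spanning
  # all major lineages) with the two regulatory subsets loading negatively,
  # giving planted negative correlations (regulatory/inhibitory edges)
  load_h <- matrix(0, k, 1, dimnames = list(subsets, NULL))
  web <- c("Central memory CD4", "Temra CD4", "Tbet+CD244+ temra CD8",
           "CD56dim NK", "gdT", "Classical monocyte", "Naive B",
           "GATA3+CD56++ NK")
  load_h[web, 1] <- 0.88
  load_h[c("FoxP3+CD25+CTLA4+ naive Treg", "PD1+CTLA4+TIGIT+ em CD4"), 1] <-
    -0.82
  corr_h <- .factor_corr(load_h)

  # sepsis: two restricted, all-positive T-cell modules (a CD4 module and a
  # CD8 module), no cross-lineage web and no negative loadings
  load_s <- matrix(0, k, 2, dimnames = list(subsets, NULL))
  load_s[c("Central memory CD4", "Temra CD4", "PD1+CTLA4+TIGIT+ em CD4",
           "IL8+ naive CD4"), 1] <- 0.9
  load_s[c("IL8+ naive CD8", "Tbet+CD244+ temra CD8", "Naive CD8"), 2] <- 0.9
  corr_s <- .factor_corr(load_s)

  sig_h <- sigma_log^2 * corr_h
  sig_s <- sigma_log^2 * corr_s

  delta0 <- target_d * sigma_log
  cal <- .calibrate_shifts(mu, delta0, sig_h, sig_s, target_d)

  couplings <- data.frame(
    subset = c("CD15+CD14+ monocyte", "CD45RA-IL17A+CD4+ T"),
    variable = c("procalcitonin", "lactate"),
    r = c(0.68, 0.57),
    stringsAsFactors = FALSE
  )
  lab_models <- list(
    procalcitonin = list(mean = 25, sd = 10, min = 0.01),
    lactate = list(mean = 2.5, sd = 0.9, min = 0.1),
    crp = list(mean = 120, sd = 55, min = 1),
    wbc = list(mean = 12, sd = 5, min = 0.5)
  )

  # outcomes: logistic link on standardised frequencies of the three subsets
  # retained after validation (monocyte, Th17, CX3CR1+CTLA4+ CD4) plus a
  # small Ki67+ B term; intercepts calibrated to the target prevalences
  om_pred <- subsets[1:4]
  om_coef <- list(
    severe_sepsis = c(1.0, 0.8, 0.7, 0.3),
    septic_shock = c(0.9, 0.8, 0.6, 0.2),
    multiorgan_dysfunction = c(0.9, 0.7, 0.6, 0.2),
    picu_mortality = c(0.8, 0.9, 0.5, 0.0)
  )
  fm_s <- cal$freq_moments$sepsis
  zcal <- with_seed_opt(.CALIBRATION_SEED + 999L, {
    f <- 100 * close_compositions(
      MASS::mvrnorm(.CALIBRATION_N, mu + cal$delta, sig_s))
    scale(f[, om_pred],
          center = fm_s$mean[om_pred], scale = fm_s$sd[om_pred])
  })
  lin <- lapply(om_coef, function(b) drop(zcal %*% b))
  prev <- c(severe_sepsis = 0.746, septic_shock = 0.729,
            multiorgan_dysfunction = 0.695, picu_mortality = 0.136)
  intercepts <- vapply(names(om_coef), function(o) {
    .calibrate_intercept(lin[[o]], prev[[o]])
  }, numeric(1))
  outcome_model <- list(predictors = om_pred, coef = om_coef,
                        intercepts = intercepts, prevalence = prev,
                        lin_sd = vapply(lin, sd, numeric(1)),
                        latent_rho = 0.5)

  # age brackets (years): draws give ~74% of sepsis subjects above 1 year
  age_model <- list(
    breaks = c(0, 1 / 12, 1, 12, 16),
    sepsis = c(0.020, 0.236, 0.522, 0.222),
    healthy = c(0.060, 0.203, 0.637, 0.100)
  )

  n <- if (cohort == "discovery") c(39L, 19L) else c(20L, 15L)
  cohort_scenario(
    name = cohort,
    n_sepsis = n[1], n_healthy = n[2],
    archetypes = arch,
    base_logratio_mean = mu,
    group_shift = cal$delta,
    covariance_healthy = sig_h,
    covariance_sepsis = sig_s,
    target_d = target_d,
    clinical_couplings = couplings,
    lab_models = lab_models,
    outcome_model = outcome_model,
    age_model = age_model,
    freq_moments = cal$freq_moments,
    events_per_subject = events_per_subject,
    panel = panel,
    seed = seed
  )
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("<cohort_scenario> ", x$name, ": ", x$n_sepsis, " sepsis + ",
      x$n_healthy, " healthy subjects, ", length(x$subsets),
      " subsets, ", x$events_per_subject, " events/subject\n", sep = "")
  cat("  enriched: ", sum(x$group_shift > 0), ", depleted: ",
      sum(x$group_shift < 0), "\n", sep = "")
  invisible(x)
}
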