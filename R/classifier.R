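# Subset-frequency diagnostic/prognostic models, ROC evaluation and the
# cohort summary table.

#' Specify a subset-frequency classifier
#'
#' @param predictors character vector of subset names (columns of the
#'   frequency table) and/or clinical covariates (e.g. `"age_years"`).
#' @param outcome one of `"sepsis"` (sepsis vs healthy over the whole
#'   cohort), `"severe_sepsis"`, `"septic_shock"`, `"picu_mortality"`,
#'   `"multiorgan_dysfunction"` (within sepsis subjects).
#' @param adjust_age add `age_years` as a covariate (default `TRUE`).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(predictors,
                       outcome = c("sepsis", "severe_sepsis", "septic_shock",
                                   "picu_mortality",
                                   "multiorgan_dysfunction"),
                       adjust_age = TRUE) {
  outcome <- match.arg(outcome)
  if (adjust_age && !"age_years" %in% predictors) {
    predictors <- c(predictors, "age_years")
  }
  structure(list(predictors = predictors, outcome = outcome,
                 adjust_age = adjust_age),
            class = "model_spec")
}

#' Default subset-model specifications
#'
#' The four-subset model combines the four subsets enriched in sepsis
#' (CD15+CD14+ monocytes, memory Th17 cells, CD45RA-CX3CR1+CTLA4+ CD4 T
#' cells, Ki67+ B cells) adjusted for age; the three-subset variant drops
#' the Ki67+ B cells (the subset not confirmed on orthogonal validation).
#'
#' @param model `"4subset"` or `"3subset"`.
#' @param outcome passed to [model_spec()].
#' @param adjust_age passed to [model_spec()].
#' @return a `model_spec`.
#' @export
default_model_spec <- function(model = c("4subset", "3subset"),
                               outcome = "sepsis", adjust_age = TRUE) {
  model <- match.arg(model)
  subsets <- c("CD15+CD14+ monocyte", "CD45RA-IL17A+CD4+ T",
               "CD45RA-CX3CR1+CTLA4+CD4+ T", "Ki67+ B")
  if (model == "3subset") subsets <- subsets[1:3]
  model_spec(subsets, outcome = outcome, adjust_age = adjust_age)
}

# penalised logistic fit by IRLS (ridge on non-intercept coefficients);
# fallback when the unpenalised likelihood does not exist (separation)
.ridge_logistic <- function(x, y, lambda = 1e-2, iters = 100L) {
  x1 <- cbind(1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (i in seq_len(iters)) {
    eta <- drop(x1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x1 * w)
    beta_new <- solve(xtw %*% x1 + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(coefficients = drop(beta),
       fitted = plogis(drop(x1 %*% beta)))
}

#' Fit a logistic subset-frequency model
#'
#' Logistic regression of the outcome on the listed subset frequencies and
#' covariates; per-subject scores are the fitted probabilities.  The fit is
#' deterministic.  Perfect separation is flagged and handled by a ridge
#' penalised fallback so scores are still produced.
#'
#' @param spec a [model_spec()].
#' @param freqs a `subset_frequencies` object.
#' @param clinical clinical data.frame (`subject_id`, `age_years`, outcome
#'   columns).
#' @return object of class `subset_model`: `spec`, `coefficients`, `scores`
#'   (named per subject), `labels`, `separation` flag, `data`.
#' @export
fit_subset_model <- function(spec, freqs, clinical) {
  ids <- rownames(freqs$freq)
  cl <- clinical[match(ids, clinical$subject_id), , drop = FALSE]
  df <- data.frame(row.names = ids, check.names = FALSE)
  for (pr in spec$predictors) {
    if (pr %in% colnames(freqs$freq)) {
      df[[pr]] <- freqs$freq[, pr]
    } else if (pr %in% colnames(cl)) {
      df[[pr]] <- cl[[pr]]
    } else {
      stop("predictor not found in frequency or clinical table: ", pr,
           call. = FALSE)
    }
  }
  if (spec$outcome == "sepsis") {
    y <- freqs$group == "sepsis"
  } else {
    keep <- freqs$group == "sepsis"
    df <- df[keep, , drop = FALSE]
    cl <- cl[keep, , drop = FALSE]
    y <- as.logical(cl[[spec$outcome]])
  }
  if (length(unique(y)) < 2) {
    stop("outcome '", spec$outcome, "' has a single class", call. = FALSE)
  }
  x <- as.matrix(df)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(`(Intercept)` = 1, x), y,
            family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (separation) {
    rf <- .ridge_logistic(x, as.numeric(y))
    coefs <- setNames(rf$coefficients, c("(Intercept)", colnames(x)))
    scores <- setNames(rf$fitted, rownames(df))
  } else {
    coefs <- fit$coefficients
    scores <- setNames(fit$fitted.values, rownames(df))
  }
  structure(
    list(spec = spec, coefficients = coefs, scores = scores,
         labels = setNames(y, rownames(df)), separation = separation,
         data = df),
    class = "subset_model"
  )
}

#' @export
print.subset_model <- function(x, ...) {
  cat("<subset_model> outcome ", x$spec$outcome, ", ",
      length(x$scores), " subjects",
      if (x$separation) " [separation: ridge fallback]", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# trapezoidal ROC curve over all score thresholds
.roc_curve <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' ROC metrics for a score vector
#'
#' AUC by the trapezoidal rule over all score thresholds (identical to the
#' Mann-Whitney rank estimator), a DeLong-style asymptotic confidence
#' interval from the paired-placement covariance, a cutoff chosen by
#' Youden's J (ties resolve to the highest threshold), and the
#' sensitivity / specificity / PPV / NPV and confusion counts at that
#' cutoff.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; `TRUE` = case.
#' @param conf confidence level (default 0.95).
#' @return object of class `classifier_metrics`: `auc`, `auc_lower`,
#'   `auc_upper`, `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (all rates in [0, 1]), confusion counts `tp`, `fp`, `tn`, `fn`,
#'   `n_cases`, `n_controls`, and the ROC `curve`.
#' @export
roc_metrics <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  curve <- .roc_curve(scores, labels)
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  # DeLong placements
  s1 <- scores[labels]; s0 <- scores[!labels]
  v10 <- vapply(s1, function(a) mean((a > s0) + 0.5 * (a == s0)), numeric(1))
  v01 <- vapply(s0, function(b) mean((s1 > b) + 0.5 * (s1 == b)), numeric(1))
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - conf) / 2)
  # Youden cutoff (finite thresholds only)
  fin <- is.finite(curve$threshold)
  j <- curve$tpr[fin] - curve$fpr[fin]
  best <- which.max(j)   # thresholds sorted decreasing: first max = highest
  cutoff <- curve$threshold[fin][best]
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  structure(
    list(
      auc = auc,
      auc_lower = max(0, auc - z * se), auc_upper = min(1, auc + z * se),
      auc_se = se, cutoff = cutoff,
      sensitivity = tp / n1, specificity = tn / n0,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      tp = tp, fp = fp, tn = tn, fn = fn,
      n_cases = n1, n_controls = n0,
      curve = curve
    ),
    class = "classifier_metrics"
  )
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "<classifier_metrics> AUC %.3f (95%% CI %.3f-%.3f); at cutoff %.3g: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%% (%d cases / %d controls)\n",
    x$auc, x$auc_lower, x$auc_upper, x$cutoff, 100 * x$sensitivity,
    100 * x$specificity, 100 * x$ppv, 100 * x$npv, x$n_cases, x$n_controls))
  invisible(x)
}

#' Predictive values implied by sensitivity and specificity
#'
#' Reconstructs the confusion matrix from a reported sensitivity and
#' specificity applied to given case/control counts (counts rounded to
#' integers) and recomputes the positive and negative predictive values --
#' the internal-consistency check connecting the four reported rates.
#'
#' @param sensitivity,specificity rates, as fractions (0.872) or percent
#'   (87.2).
#' @param n_cases,n_controls class sizes.
#' @return list with integer `tp`, `fp`, `tn`, `fn` and `ppv`, `npv` in
#'   percent.
#' @export
#' @examples
#' predictive_values(87.2, 79.0, 39, 19)
predictive_values <- function(sensitivity, specificity, n_cases,
                              n_controls) {
  if (sensitivity > 1) sensitivity <- sensitivity / 100
  if (specificity > 1) specificity <- specificity / 100
  tp <- round(sensitivity * n_cases)
  fn <- n_cases - tp
  tn <- round(specificity * n_controls)
  fp <- n_controls - tn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn))
}

#' ROC metrics of clinical comparators
#'
#' Single-variable ROC for the clinical severity scores and laboratory
#' markers (pSOFA, PELOD-2, PIM-3, CRP, procalcitonin, lactate) against an
#' outcome among sepsis subjects, with the same metric contract as the
#' subset models.  Variables that are entirely missing are skipped with a
#' warning.
#'
#' @param clinical clinical data.frame.
#' @param outcome outcome column (default `"picu_mortality"`).
#' @param variables comparator columns.
#' @return named list of `classifier_metrics`.
#' @export
comparator_models <- function(clinical, outcome = "picu_mortality",
                              variables = c("psofa", "pelod2", "pim3",
                                            "crp", "procalcitonin",
                                            "lactate")) {
  cl <- clinical[clinical$group == "sepsis", , drop = FALSE]
  y <- as.logical(cl[[outcome]])
  out <- list()
  for (v in variables) {
    vals <- cl[[v]]
    ok <- !is.na(vals)
    if (!any(ok)) {
      warning("comparator '", v, "' is entirely missing; skipped",
              call. = FALSE)
      next
    }
    out[[v]] <- roc_metrics(vals[ok], y[ok])
  }
  out
}

#' Cohort summary table
#'
#' Median (IQR) per group for continuous variables and n (%) for categorical
#' and logical variables, percentages to one decimal -- the standard
#' clinical Table-1 layout.  Empty strata are emitted as `n = 0 (0.0%)`.
#'
#' @param clinical clinical data.frame.
#' @param continuous,categorical column names to summarise (defaults cover
#'   the generated record schema).
#' @return data.frame with columns `group`, `variable`, `level`, `n`, `pct`,
#'   `median`, `q1`, `q3`, `summary` (formatted string).
#' @export
cohort_summary <- function(clinical,
                           continuous = c("age_years", "wbc", "crp",
                                          "procalcitonin", "lactate",
                                          "psofa", "pelod2", "pim3"),
                           categorical = c("site_of_infection",
                                           "severe_sepsis", "septic_shock",
                                           "multiorgan_dysfunction",
                                           "picu_mortality")) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (g in unique(clinical$group)) {
    cg <- clinical[clinical$group == g, , drop = FALSE]
    n_g <- nrow(cg)
    for (v in intersect(continuous, colnames(cg))) {
      vals <- cg[[v]][!is.na(cg[[v]])]
      if (!length(vals)) next
      q <- quantile(vals, c(.25, .5, .75))
      add(group = g, variable = v, level = NA_character_,
          n = length(vals), pct = NA_real_,
          median = q[[2]], q1 = q[[1]], q3 = q[[3]],
          summary = sprintf("%.1f (%.1f, %.1f)", q[[2]], q[[1]], q[[3]]))
    }
    for (v in intersect(categorical, colnames(cg))) {
      vals <- cg[[v]]
      if (is.logical(vals)) {
        k <- sum(vals, na.rm = TRUE)
        p <- if (n_g > 0) pct1(k, n_g) else 0
        add(group = g, variable = v, level = "TRUE", n = k, pct = p,
            median = NA_real_, q1 = NA_real_, q3 = NA_real_,
            summary = sprintf("%d (%.1f)", k, p))
      } else {
        lev <- unique(vals[!is.na(vals)])
        if (!length(lev)) {
          add(group = g, variable = v, level = NA_character_, n = 0L,
              pct = 0, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
              summary = "0 (0.0)")
          next
        }
        for (l in lev) {
          k <- sum(vals == l, na.rm = TRUE)
          p <- pct1(k, n_g)
          add(group = g, variable = v, level = as.character(l), n = k,
              pct = p, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
              summary = sprintf("%d (%.1f)", k, p))
        }
      }
    }
  }
  do.call(rbind, rows)
}
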