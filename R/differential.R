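# Differential abundance: Mann-Whitney tests with Bonferroni control,
# Cohen's d effect sizes, age stratification, and clinical correlations.

#' Cohen's d with a normal-approximation confidence interval
#'
#' Classical pooled-SD standardised mean difference.  Sign convention:
#' positive means higher in the first group.  The CI uses the standard
#' large-sample variance of d, `(n1+n2)/(n1*n2) + d^2 / (2*(n1+n2))`.
#' Hedges' small-sample correction is available by flag.
#'
#' @param x,y numeric vectors (group 1 and group 2).
#' @param conf confidence level (default 0.95).
#' @param hedges apply Hedges' g correction (default `FALSE`).
#' @return list with `d`, `lower`, `upper`, `se`; `d` is `NA` (flagged via
#'   `degenerate = TRUE`) when the pooled SD is zero.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(0, 1, 2))
cohens_d <- function(x, y, conf = 0.95, hedges = FALSE) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    return(list(d = NA_real_, lower = NA_real_, upper = NA_real_,
                se = NA_real_, degenerate = TRUE))
  }
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - conf) / 2)
  list(d = d, lower = d - z * se, upper = d + z * se, se = se,
       degenerate = FALSE)
}

.mw_test <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact,
                alternative = "two.sided")
  )
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Per-subset differential abundance between sepsis and healthy
#'
#' Two-sided Mann-Whitney U test per subset (exact when both groups have at
#' most 8 subjects and there are no ties, otherwise the normal approximation
#' with tie and continuity correction), Bonferroni-adjusted over the number
#' of subsets tested, plus Cohen's d with 95% CI.  The significance flag is
#' applied to the adjusted p-value at `alpha` (default 0.1, the type-I
#' threshold paired with the correction).
#'
#' @param freqs a `subset_frequencies` object, or a matrix with `group`.
#' @param group optional group vector when `freqs` is a matrix.
#' @param alpha adjusted-p significance threshold (default 0.1).
#' @param hedges apply Hedges' correction to d.
#' @return data.frame of class `differential_result`, one row per subset:
#'   medians and IQRs per group, `u`, `p_raw`, `p_adj`, `m`, `direction`,
#'   `d`, `d_lower`, `d_upper`, `significant`, `significant_raw`.
#' @export
test_subsets <- function(freqs, group = NULL, alpha = 0.1, hedges = FALSE) {
  if (inherits(freqs, "subset_frequencies")) {
    group <- freqs$group
    x <- freqs$freq
  } else {
    x <- as.matrix(freqs)
  }
  group <- as.character(group)
  s <- group == "sepsis"; h <- group == "healthy"
  if (sum(s) < 2 || sum(h) < 2) {
    stop("each group needs at least 2 subjects (", sum(s), " sepsis, ",
         sum(h), " healthy)", call. = FALSE)
  }
  m <- ncol(x)
  rows <- lapply(seq_len(m), function(j) {
    xs <- x[s, j]; xh <- x[h, j]
    mw <- .mw_test(xs, xh)
    d <- cohens_d(xs, xh, hedges = hedges)
    data.frame(
      subset = colnames(x)[j],
      median_sepsis = median(xs), iqr_lo_sepsis = quantile(xs, .25),
      iqr_hi_sepsis = quantile(xs, .75),
      median_healthy = median(xh), iqr_lo_healthy = quantile(xh, .25),
      iqr_hi_healthy = quantile(xh, .75),
      u = mw$u, p_raw = mw$p, p_adj = min(1, mw$p * m), m = m,
      d = d$d, d_lower = d$lower, d_upper = d$upper,
      direction = if (is.na(d$d)) NA_character_ else
        if (d$d >= 0) "up" else "down",
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out$significant_raw <- out$p_raw < alpha
  class(out) <- c("differential_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Age-stratified sensitivity analysis
#'
#' Partitions subjects at `cut` years (default 1) and reruns
#' [test_subsets()] within each stratum; a stratum with fewer than 2
#' subjects in either group is skipped with a warning.
#'
#' @param freqs a `subset_frequencies` object.
#' @param clinical clinical data.frame with `subject_id` and `age_years`.
#' @param cut age cut in years (default 1).
#' @param alpha adjusted-p threshold.
#' @return named list with elements `over` (age > cut) and `under`
#'   (age <= cut), each a `differential_result` or `NULL` if skipped, plus
#'   `strata_n` (per-stratum group sizes).
#' @export
stratify_by_age <- function(freqs, clinical, cut = 1, alpha = 0.1) {
  age <- clinical$age_years[match(rownames(freqs$freq),
                                  clinical$subject_id)]
  if (anyNA(age)) stop("missing ages for some subjects", call. = FALSE)
  strata <- list(over = age > cut, under = age <= cut)
  n_tab <- lapply(strata, function(keep) table(freqs$group[keep]))
  res <- lapply(names(strata), function(nm) {
    keep <- strata[[nm]]
    tab <- table(factor(freqs$group[keep], levels = c("healthy", "sepsis")))
    if (any(tab < 2)) {
      warning("stratum '", nm, "' skipped: fewer than 2 subjects per group",
              call. = FALSE)
      return(NULL)
    }
    test_subsets(subset_frequencies(freqs$freq[keep, , drop = FALSE],
                                    freqs$group[keep]), alpha = alpha)
  })
  names(res) <- names(strata)
  res$strata_n <- n_tab
  res
}

#' Correlations between subset frequencies and clinical variables
#'
#' Computed over sepsis subjects (laboratory values are absent for healthy
#' controls): Pearson for continuous laboratory values (CRP, procalcitonin,
#' lactate, WBC) and Spearman for ordinal severity scores (pSOFA, PELOD-2,
#' PIM-3), with pairwise-complete observations.  Estimates are withheld when
#' fewer than 3 complete pairs are available.
#'
#' @param freqs a `subset_frequencies` object.
#' @param clinical clinical data.frame.
#' @param subsets subset columns to correlate (default all).
#' @param variables named character vector mapping clinical columns to
#'   `"pearson"` or `"spearman"` (default: the standard assignment above).
#' @return data.frame of class `correlation_result` with columns `subset`,
#'   `variable`, `method`, `estimate`, `p`, `n`.
#' @export
clinical_correlations <- function(freqs, clinical,
                                  subsets = colnames(freqs$freq),
                                  variables = c(
                                    crp = "pearson",
                                    procalcitonin = "pearson",
                                    lactate = "pearson",
                                    wbc = "pearson",
                                    psofa = "spearman",
                                    pelod2 = "spearman",
                                    pim3 = "spearman"
                                  )) {
  keep <- freqs$group == "sepsis"
  ids <- rownames(freqs$freq)[keep]
  cl <- clinical[match(ids, clinical$subject_id), , drop = FALSE]
  x <- freqs$freq[keep, subsets, drop = FALSE]
  variables <- variables[names(variables) %in% colnames(cl)]
  out <- list()
  for (v in names(variables)) {
    for (s in subsets) {
      ok <- complete.cases(x[, s], cl[[v]])
      n_ok <- sum(ok)
      if (n_ok < 3) {
        est <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          cor.test(x[ok, s], cl[[v]][ok], method = variables[[v]],
                   exact = FALSE)
        )
        est <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        subset = s, variable = v, method = variables[[v]],
        estimate = est, p = p, n = n_ok, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_result", "data.frame")
  res
}
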