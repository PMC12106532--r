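# Subject-level PCA with loadings and a seeded event-level 2-D embedding.

#' Subject-level principal component analysis of subset frequencies
#'
#' Subjects are observations, subsets are variables.  Columns are centred and
#' (by default) unit-scaled, with a variance floor guarding constant columns
#' (scaled by 1 with a warning).  Any component pair can be extracted -- the
#' separation of sepsis from healthy subjects is often clearest off the first
#' pair (e.g. PC1 vs PC3).
#'
#' @param freqs a `subset_frequencies` object or bare matrix.
#' @param scale. unit-scale columns (default `TRUE`).
#' @param components component pair to report as `component_pair_used`.
#' @return object of class `pca_result`: `scores`, `loadings` (unit-norm
#'   columns), `variance_explained`, `component_pair_used`, `center`,
#'   `scale`, `group`.
#' @export
subject_pca <- function(freqs, scale. = TRUE, components = c(1L, 2L)) {
  x <- if (inherits(freqs, "subset_frequencies")) freqs$freq else
    as.matrix(freqs)
  if (nrow(x) < 3) stop("need at least 3 subjects for PCA", call. = FALSE)
  grp <- if (inherits(freqs, "subset_frequencies")) freqs$group else NULL
  sds <- apply(x, 2L, sd)
  scl <- FALSE
  if (isTRUE(scale.)) {
    if (any(sds <= 1e-12)) {
      warning("constant column(s) detected; variance floor applied: ",
              paste(colnames(x)[sds <= 1e-12], collapse = ", "),
              call. = FALSE)
      sds[sds <= 1e-12] <- 1
    }
    scl <- sds
  }
  pc <- prcomp(x, center = TRUE, scale. = scl)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x, loadings = pc$rotation,
         variance_explained = ve,
         component_pair_used = as.integer(components),
         center = pc$center, scale = pc$scale, group = grp),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  i <- x$component_pair_used
  cat("<pca_result> ", nrow(x$scores), " subjects, components ", i[1],
      " and ", i[2], " explain ",
      round(100 * sum(x$variance_explained[i]), 1), "% of variance\n",
      sep = "")
  invisible(x)
}

# Perplexity-calibrated input affinities for t-SNE: binary search on the
# per-point precision so the conditional distribution has the requested
# perplexity, then symmetrise.
.tsne_affinities <- function(d2, perplexity, tol = 1e-5) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) sw <- .Machine$double.xmin
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - log_u) < tol) break
      if (h > log_u) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sw
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, .Machine$double.xmin)
}

#' Event-level two-dimensional embedding (exact t-SNE)
#'
#' Seeded black-box 2-D embedding for visual structure checks: the input is
#' first reduced to its top principal components, then embedded with an
#' exact (quadratic-cost) t-SNE.  Intended for downsampled event sets (a few
#' thousand events); embedding quality is assessed downstream only through
#' label-based statistics, never through coordinate values.
#'
#' @param x numeric matrix (events x markers, asinh scale) or
#'   `pooled_events`.
#' @param perplexity t-SNE perplexity (default 30; must be < number of
#'   events).
#' @param n_pcs PCA pre-reduction dimension (default `min(10, ncol)`).
#' @param n_iter gradient-descent iterations (default 300).
#' @param init `"pca"` (default; deterministic start from the first two PCs
#'   plus seeded jitter) or `"random"`.
#' @param seed integer seed.
#' @return object of class `embedding_result`: `coordinates` (events x 2),
#'   `seed`, `perplexity`, `init`.
#' @export
event_embedding <- function(x, perplexity = 30, n_pcs = NULL, n_iter = 300L,
                            init = c("pca", "random"), seed = 1L) {
  init <- match.arg(init)
  if (inherits(x, "pooled_events")) x <- x$exprs
  x <- as.matrix(x)
  n <- nrow(x)
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be smaller than the number of events (",
         n, ")", call. = FALSE)
  }
  n_pcs <- n_pcs %||% min(10L, ncol(x))
  pc <- prcomp(x, center = TRUE, rank. = n_pcs)
  z <- pc$x
  d2 <- as.matrix(dist(z))^2
  p <- .tsne_affinities(d2, perplexity)
  y <- with_seed_opt(seed, {
    if (init == "pca") {
      y0 <- pc$x[, 1:2, drop = FALSE]
      y0 <- y0 / sd(y0[, 1]) * 1e-4
      y0 + matrix(rnorm(2 * n, sd = 1e-6), n, 2)
    } else {
      matrix(rnorm(2 * n, sd = 1e-4), n, 2)
    }
  })
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exaggeration <- 4
  for (it in seq_len(n_iter)) {
    pp <- if (it <= 50) p * exaggeration else p
    num <- 1 / (1 + as.matrix(dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), .Machine$double.xmin)
    w <- (pp - q) * num
    grad <- 4 * (diag(rowSums(w)) %*% y - w %*% y)
    momentum <- if (it <= 20) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - 200 * gain * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  structure(
    list(coordinates = y, seed = seed, perplexity = perplexity, init = init),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$coordinates),
      " events, perplexity ", x$perplexity, ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
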