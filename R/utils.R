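#' @importFrom stats median quantile sd var cor cor.test wilcox.test prcomp
#'   rnorm rlnorm runif rbinom plogis qnorm pnorm pt uniroot setNames
#'   complete.cases mahalanobis dist hclust cutree as.dist aggregate
#' @importFrom utils write.table read.table head modifyList
NULL

#' Evaluate an expression under a local seed
#'
#' All stochastic operations in the package accept an explicit `seed`.  When
#' it is non-`NULL` the draw happens inside [withr::with_seed()] so the
#' caller's RNG stream is untouched; when `NULL` the current stream is used.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed derivation so one master seed reproduces an entire
#' multi-stage run.  Stage names are hashed with a small FNV-1a style mix and
#' folded into the 31-bit range R accepts in [set.seed()].
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"cluster"`), or an integer index.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 2166136261
  bytes <- utf8ToInt(paste0("s", as.character(stage)))
  for (b in bytes) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a covariance matrix is symmetric positive semi-definite
#' @keywords internal
assert_psd <- function(sigma, label = "covariance", tol = 1e-8) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop(label, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8) {
    stop(label, " must be symmetric", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(label, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Percentage formatted to one decimal, as the number it prints
#' @keywords internal
pct1 <- function(k, n) round(100 * k / n, 1)
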