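# Batch self-organising map over a rectangular grid, with deterministic
# tie-breaking (equidistant codebook vectors resolve to the lowest node
# index) and seeded initialisation from sampled events.

# squared Euclidean distances between rows of x and rows of w, chunked so the
# full n x m distance matrix never exceeds ~8M doubles
.nearest_node <- function(x, w, chunk = 200000L %/% max(nrow(w), 1L)) {
  n <- nrow(x)
  w2 <- rowSums(w^2)
  out <- integer(n)
  chunk <- max(chunk, 1L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- -2 * x[idx, , drop = FALSE] %*% t(w)
    d <- sweep(d, 2L, w2, `+`)
    out[idx] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Fit a self-organising map to pooled events
#'
#' Batch SOM on a `grid_rows` x `grid_cols` rectangular grid: codebook
#' vectors are initialised from a seeded sample of events, then updated for
#' `epochs` rounds as Gaussian-neighbourhood-weighted means of the events
#' mapped to each node, with the neighbourhood radius decaying linearly.
#' Given the seed the fit is fully deterministic; event-to-node assignment is
#' nearest codebook vector by Euclidean distance with ties resolved to the
#' lowest node index.
#'
#' @param x numeric matrix (events x markers) on the asinh scale, or a
#'   `pooled_events` object.
#' @param grid_rows,grid_cols grid dimensions (default 10 x 10, i.e. 100
#'   nodes).
#' @param epochs training rounds (default 14).
#' @param radius_start,radius_end neighbourhood radius schedule (defaults:
#'   half the grid diagonal decaying linearly to 0.2, so late epochs refine
#'   each node almost independently).
#' @param seed integer seed for the codebook initialisation.
#' @return object of class `som_fit`: `codebook` (nodes x markers), `grid`
#'   (node coordinates), `assignment` (per-event node), `grid_rows`,
#'   `grid_cols`.
#' @export
som_fit <- function(x, grid_rows = 10L, grid_cols = 10L, epochs = 14L,
                    radius_start = NULL, radius_end = 0.2, seed = NULL) {
  if (inherits(x, "pooled_events")) x <- x$exprs
  x <- as.matrix(x)
  m <- grid_rows * grid_cols
  if (nrow(x) < m) {
    stop("fewer events (", nrow(x), ") than SOM nodes (", m, ")",
         call. = FALSE)
  }
  grid <- as.matrix(expand.grid(row = seq_len(grid_rows),
                                col = seq_len(grid_cols)))
  gd2 <- as.matrix(dist(grid))^2
  radius_start <- radius_start %||%
    (sqrt(grid_rows^2 + grid_cols^2) / 2)
  codebook <- with_seed_opt(seed, x[sample.int(nrow(x), m), , drop = FALSE])
  for (e in seq_len(epochs)) {
    r <- radius_start + (radius_end - radius_start) * (e - 1) /
      max(epochs - 1, 1)
    bmu <- .nearest_node(x, codebook)
    cnt <- tabulate(bmu, nbins = m)
    sums <- rowsum(x, bmu, reorder = FALSE)
    full_sums <- matrix(0, m, ncol(x))
    full_sums[as.integer(rownames(sums)), ] <- sums
    h <- exp(-gd2 / (2 * r^2))
    denom <- drop(h %*% cnt)
    num <- h %*% full_sums
    upd <- denom > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  assignment <- .nearest_node(x, codebook)
  rownames(codebook) <- paste0("node", seq_len(m))
  colnames(codebook) <- colnames(x)
  structure(
    list(codebook = codebook, grid = grid, assignment = assignment,
         grid_rows = grid_rows, grid_cols = grid_cols),
    class = "som_fit"
  )
}

#' Assign events to their nearest SOM codebook vector
#'
#' @param som a `som_fit`.
#' @param x numeric matrix on the same scale as the training data.
#' @return integer vector of node indices (ties to the lowest index).
#' @export
som_assign <- function(som, x) {
  if (inherits(x, "pooled_events")) x <- x$exprs
  .nearest_node(as.matrix(x), som$codebook)
}

#' @export
print.som_fit <- function(x, ...) {
  cat("<som_fit> ", x$grid_rows, "x", x$grid_cols, " grid (",
      nrow(x$codebook), " nodes), ", length(x$assignment),
      " events assigned\n", sep = "")
  invisible(x)
}
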