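# Event matrices and preprocessing: asinh transform, per-subject
# downsampling, cohort concatenation, and the TSV event dialect.

#' Construct an event matrix
#'
#' Single-subject single-cell intensity matrix with provenance.  Raw-scale
#' matrices must be non-negative; the `scale` flag records whether the asinh
#' transform has been applied (and with which cofactor) so it cannot be
#' applied twice.
#'
#' @param exprs numeric matrix, events x markers (column names required).
#' @param subject_id subject identifier.
#' @param group `"sepsis"` or `"healthy"`.
#' @param scale `"raw"` or `"asinh<cofactor>"` (e.g. `"asinh5"`).
#' @param labels optional integer/character vector of true population labels
#'   per event (kept for recovery testing with synthetic data).
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(exprs, subject_id, group = NA_character_,
                         scale = "raw", labels = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs))) stop("exprs must have marker column names")
  if (identical(scale, "raw") && any(exprs < 0)) {
    stop("raw-scale intensities must be non-negative", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != nrow(exprs)) {
    stop("labels length must match event count")
  }
  structure(
    list(exprs = exprs, subject_id = subject_id, group = group,
         scale = scale, labels = labels),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("<event_matrix> ", x$subject_id, " (", x$group, "): ",
      nrow(x$exprs), " events x ", ncol(x$exprs), " markers [",
      x$scale, "]\n", sep = "")
  invisible(x)
}

#' Hyperbolic arcsine transform of an event matrix
#'
#' Applies `asinh(x / cofactor)` to every intensity, the standard
#' variance-stabilising transform for cytometry (cofactor 5 for mass
#' cytometry).  Refuses to transform a matrix that is already on a
#' transformed scale.
#'
#' @param x an `event_matrix` on the raw scale, or a bare numeric matrix.
#' @param cofactor positive scale factor (default 5).
#' @return the transformed `event_matrix` (or matrix), with the scale flag
#'   updated to `"asinh<cofactor>"`.
#' @seealso [asinh_inverse()]
#' @export
#' @examples
#' asinh_transform(matrix(5, 1, 1, dimnames = list(NULL, "CD3")))  # log(1+sqrt(2))
asinh_transform <- function(x, cofactor = 5) {
  stopifnot(cofactor > 0)
  if (inherits(x, "event_matrix")) {
    if (!identical(x$scale, "raw")) {
      stop("event matrix is already on scale '", x$scale,
           "'; refusing to transform twice", call. = FALSE)
    }
    x$exprs <- asinh(x$exprs / cofactor)
    x$scale <- sprintf("asinh%g", cofactor)
    return(x)
  }
  if (any(x < 0)) stop("raw intensities must be non-negative", call. = FALSE)
  asinh(x / cofactor)
}

#' Inverse of the asinh transform
#'
#' @param x a transformed `event_matrix` or numeric matrix.
#' @param cofactor the cofactor used for the forward transform.
#' @return raw-scale values, `cofactor * sinh(y)`.
#' @export
asinh_inverse <- function(x, cofactor = 5) {
  if (inherits(x, "event_matrix")) {
    if (!identical(x$scale, sprintf("asinh%g", cofactor))) {
      stop("event matrix scale '", x$scale, "' does not match cofactor ",
           cofactor, call. = FALSE)
    }
    x$exprs <- cofactor * sinh(x$exprs)
    x$scale <- "raw"
    return(x)
  }
  cofactor * sinh(x)
}

#' Randomly downsample an event matrix
#'
#' Uniform sampling without replacement to exactly `n_events` rows, the
#' standard per-subject equalisation before pooled clustering (50,000 events
#' by default).  Subjects with fewer events than the target are kept in full
#' under the default rule (with a warning), or rejected under `"strict"`.
#'
#' @param x an `event_matrix`.
#' @param n_events target event count (default 50000).
#' @param rule `"keep-all-if-fewer"` (default) or `"strict"`.
#' @param seed optional integer seed.
#' @return the downsampled `event_matrix` (labels subset alongside).
#' @export
downsample_events <- function(x, n_events = 50000L,
                              rule = c("keep-all-if-fewer", "strict"),
                              seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(x, "event_matrix"), n_events >= 1)
  n <- nrow(x$exprs)
  if (n < n_events) {
    if (rule == "strict") {
      stop("subject ", x$subject_id, " has only ", n, " events (< ",
           n_events, ") under strict downsampling", call. = FALSE)
    }
    warning("subject ", x$subject_id, ": ", n, " events < target ",
            n_events, "; keeping all", call. = FALSE)
    return(x)
  }
  idx <- with_seed_opt(seed, sort(sample.int(n, n_events)))
  x$exprs <- x$exprs[idx, , drop = FALSE]
  if (!is.null(x$labels)) x$labels <- x$labels[idx]
  x
}

#' Concatenate per-subject event matrices into one pooled matrix
#'
#' All inputs must share the marker panel and scale.  Row order is the input
#' order (subjects in sequence, events in their original order), and each
#' row keeps its subject and group provenance.
#'
#' @param matrices list of `event_matrix` objects.
#' @return an object of class `pooled_events`: list with `exprs`,
#'   per-row `subject`, `group`, optional `labels`, and the common `scale`.
#' @export
concatenate_events <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  panels <- lapply(matrices, function(m) colnames(m$exprs))
  ok <- vapply(panels, identical, logical(1), panels[[1]])
  if (!all(ok)) {
    bad <- vapply(matrices[!ok], `[[`, character(1), "subject_id")
    stop("marker panel mismatch for subjects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  scales <- vapply(matrices, `[[`, character(1), "scale")
  if (length(unique(scales)) != 1L) {
    stop("mixed scales in concatenation: ",
         paste(unique(scales), collapse = ", "), call. = FALSE)
  }
  ns <- vapply(matrices, function(m) nrow(m$exprs), integer(1))
  labels <- lapply(matrices, `[[`, "labels")
  has_lab <- !vapply(labels, is.null, logical(1))
  structure(
    list(
      exprs = do.call(rbind, lapply(matrices, `[[`, "exprs")),
      subject = rep(vapply(matrices, `[[`, character(1), "subject_id"), ns),
      group = rep(vapply(matrices, function(m) as.character(m$group),
                         character(1)), ns),
      labels = if (all(has_lab)) unlist(labels, use.names = FALSE) else NULL,
      scale = scales[1]
    ),
    class = "pooled_events"
  )
}

#' @export
print.pooled_events <- function(x, ...) {
  cat("<pooled_events> ", nrow(x$exprs), " events x ", ncol(x$exprs),
      " markers from ", length(unique(x$subject)), " subjects [",
      x$scale, "]\n", sep = "")
  invisible(x)
}

#' Write an event matrix to the TSV event dialect
#'
#' One header row of marker names, one row per event; when true population
#' labels are present they are written as a final `population` column.
#'
#' @param x an `event_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(x, path) {
  df <- as.data.frame(x$exprs)
  if (!is.null(x$labels)) df$population <- x$labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event matrix from the TSV event dialect
#'
#' @param path file path.
#' @param subject_id,group provenance to attach (defaults derive the subject
#'   id from the file name).
#' @param scale scale flag of the stored values (default `"raw"`).
#' @return an `event_matrix`.
#' @export
read_event_tsv <- function(path, subject_id = NULL, group = NA_character_,
                           scale = "raw") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- NULL
  if ("population" %in% colnames(df)) {
    labels <- df$population
    df$population <- NULL
  }
  event_matrix(as.matrix(df),
               subject_id = subject_id %||%
                 sub("\\.tsv$", "", basename(path)),
               group = group, scale = scale, labels = labels)
}
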