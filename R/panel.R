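#' Multi-subject time-series panel
#'
#' Bundles one real-valued matrix per subject, each with `p` network nodes
#' (regions of interest) in rows and time points in columns.  All subjects
#' must share the same node count; the number of time points may differ
#' between subjects.
#'
#' @param subjects List of numeric matrices, one per subject, nodes x time.
#'   Vectors are treated as single-node series.
#' @param labels Optional character vector of node names, length `p`.
#' @return An object of class `ts_panel` with elements `subjects` (list of
#'   matrices), `p`, `n_s` (integer vector of per-subject time points) and
#'   `labels`.
#' @examples
#' panel <- ts_panel(list(matrix(rnorm(60), 3), matrix(rnorm(90), 3)))
#' panel$p
#' panel$n_s
#' @export
ts_panel <- function(subjects, labels = NULL) {
  if (!is.list(subjects) || length(subjects) == 0) {
    stop("`subjects` must be a non-empty list of matrices", call. = FALSE)
  }
  subjects <- lapply(subjects, function(y) {
    if (is.vector(y) && is.numeric(y)) y <- matrix(y, nrow = 1)
    if (!is.matrix(y) || !is.numeric(y)) {
      stop("each subject must be a numeric matrix", call. = FALSE)
    }
    storage.mode(y) <- "double"
    y
  })
  p <- nrow(subjects[[1]])
  ok <- vapply(subjects, nrow, integer(1)) == p
  if (!all(ok)) {
    stop("all subjects must share the same node count; subject(s) ",
         paste(which(!ok), collapse = ", "), " differ", call. = FALSE)
  }
  n_s <- vapply(subjects, ncol, integer(1))
  if (any(n_s < 2)) {
    stop("every subject needs at least 2 time points", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != p) {
    stop("`labels` must have length p = ", p, call. = FALSE)
  }
  structure(
    list(subjects = subjects, p = p, n_s = n_s, labels = labels),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> ", length(x$subjects), " subject(s), p = ", x$p,
      ", n_s = ", paste(x$n_s, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @export
length.ts_panel <- function(x) length(x$subjects)

#' Standardise a panel of time series
#'
#' Removes the temporal mean of every node in every subject and, optionally,
#' scales each node's series to unit sample variance.  All model fitting in
#' this package assumes zero-mean data, so this is the first step of every
#' pipeline.
#'
#' @param panel A [ts_panel()].
#' @param unit_variance If `TRUE`, divide each demeaned row by its sample
#'   standard deviation.  A constant (zero-variance) node is an error in this
#'   case.
#' @return A standardised `ts_panel` of the same shape.
#' @export
standardise_panel <- function(panel, unit_variance = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  panel$subjects <- lapply(panel$subjects, function(y) {
    y <- y - rowMeans(y)
    if (unit_variance) {
      sds <- apply(y, 1, stats::sd)
      if (any(sds <= 0)) {
        stop("zero-variance node encountered while scaling to unit variance",
             call. = FALSE)
      }
      y <- y / sds
    }
    y
  })
  panel
}

#' Per-subject inner-product matrices
#'
#' Computes `S_s = Y_s %*% t(Y_s)` for each subject: the p x p sample
#' inner-product (scatter) matrix that is the sufficient statistic for the
#' Gaussian likelihood.  Equal to `n_s` times the sample covariance of a
#' demeaned series.
#'
#' @param panel A standardised [ts_panel()].
#' @return An object of class `inner_products`: list with `S` (list of p x p
#'   matrices), `n_s` and `p`.
#' @export
inner_products <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  S <- lapply(panel$subjects, tcrossprod)
  structure(list(S = S, n_s = panel$n_s, p = panel$p),
            class = "inner_products")
}

#' Per-subject sample covariance matrices
#'
#' @param panel A standardised [ts_panel()].
#' @return List of p x p covariance matrices `S_s / n_s`.
#' @keywords internal
panel_covariances <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  Map(function(y, n) tcrossprod(y) / n, panel$subjects, panel$n_s)
}

#' Concatenate a panel into a single pseudo-subject
#'
#' Joins all subjects' (standardised) series along the time axis.  Used by
#' estimators that are fitted to the pooled dataset.
#'
#' @param panel A [ts_panel()].
#' @return A `ts_panel` with one subject.
#' @export
concatenate_panel <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  ts_panel(list(do.call(cbind, panel$subjects)), labels = panel$labels)
}
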