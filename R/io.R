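# delimited-text readers/writers: tab- or comma-delimited, optional header

detect_sep <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl(",", line)) "," else "\t"
}

read_numeric_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  first <- utils::read.table(path, sep = sep, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- !all(vapply(first, is.numeric, logical(1)))
  df <- utils::read.table(path, sep = sep, header = header)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric cells in ", path, call. = FALSE)
  }
  dimnames(m) <- NULL
  m
}

#' Write a matrix as tab-delimited text
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a time-series panel from a manifest
#'
#' The manifest is a comma- or tab-delimited table with a header and
#' columns `subject_id`, `path` (relative to the manifest's directory or
#' absolute) and optionally `orientation` (`"rows=roi"`, the default, or
#' `"rows=time"` for transposed files).  All files must resolve to numeric
#' matrices with a consistent node count.
#'
#' @param manifest_path Path to the manifest file.
#' @return A [ts_panel()].
#' @export
read_panel <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  sep <- detect_sep(manifest_path)
  man <- utils::read.table(manifest_path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(man))) {
    stop("manifest needs `subject_id` and `path` columns", call. = FALSE)
  }
  if (is.null(man$orientation)) man$orientation <- "rows=roi"
  base <- dirname(manifest_path)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$path[i]
    if (!file.exists(f)) f <- file.path(base, man$path[i])
    m <- read_numeric_matrix(f)
    if (identical(man$orientation[i], "rows=time")) m <- t(m)
    m
  })
  ps <- vapply(subjects, nrow, integer(1))
  if (length(unique(ps)) > 1) {
    bad <- which(ps != ps[1])[1]
    stop("inconsistent node count in ", man$path[bad], " (", ps[bad],
         " vs ", ps[1], ")", call. = FALSE)
  }
  ts_panel(subjects)
}

#' Write a panel (and manifest) to a directory
#'
#' @param panel A [ts_panel()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(panel$subjects), function(s) {
    f <- sprintf("subject_%03d.tsv", s)
    write_matrix(panel$subjects[[s]], file.path(dir, f))
    f
  }, character(1))
  man <- data.frame(subject_id = seq_along(paths), path = paths,
                    orientation = "rows=roi")
  mp <- file.path(dir, "manifest.csv")
  utils::write.table(man, mp, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Write an edge list of a symmetric matrix
#'
#' Tab-delimited columns `i`, `j`, `weight` and optionally `probability`
#' over the unordered pairs.
#'
#' @param m Symmetric matrix of edge weights.
#' @param path Output file.
#' @param prob Optional matrix of edge probabilities.
#' @export
write_edge_list <- function(m, path, prob = NULL) {
  up <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(i = up[, 1], j = up[, 2], weight = m[up])
  if (!is.null(prob)) df$probability <- prob[up]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Edge-list file.
#' @param p Node count of the reconstructed matrix (default: max index).
#' @return List with `weight` matrix and optionally `probability` matrix.
#' @export
read_edge_list <- function(path, p = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(p)) p <- max(df$i, df$j)
  w <- matrix(0, p, p)
  w[cbind(df$i, df$j)] <- df$weight
  w <- w + t(w)
  out <- list(weight = w)
  if (!is.null(df$probability)) {
    pr <- matrix(0, p, p)
    pr[cbind(df$i, df$j)] <- df$probability
    out$probability <- pr + t(pr)
  }
  out
}

#' Write a fit's draw archive as a chunked binary container
#'
#' The thinned precision draws are stored as consecutive little-endian
#' doubles in `omega.bin` (column-major, one p x p x subjects chunk per
#' draw), with dimensions, model and thinning recorded in `index.json`;
#' scalar diagnostic series go to `diagnostics.bin` in the order listed in
#' the index.  Summaries (group network and edge probabilities) are also
#' written as tab-delimited edge lists.
#'
#' @param fit A `precision_fit` with stored draws.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "precision_fit"))
  if (is.null(fit$draws)) stop("fit has no stored draws", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "omega.bin"), "wb")
  writeBin(as.vector(fit$draws), con, size = 8, endian = "little")
  close(con)
  diag_series <- list(loglik = fit$loglik)
  if (!is.null(fit$chi)) diag_series$chi <- fit$chi
  if (!is.null(fit$a)) diag_series$a <- fit$a
  con <- file(file.path(dir, "diagnostics.bin"), "wb")
  writeBin(unlist(diag_series, use.names = FALSE), con, size = 8,
           endian = "little")
  close(con)
  index <- list(
    model = fit$model,
    dim = dim(fit$draws),
    thin = fit$config$thin,
    seed = fit$config$seed,
    n_kept = fit$n_kept,
    diagnostics = lapply(diag_series, length),
    storage = "little-endian float64, column-major"
  )
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_edge_list(fit$group_pcorr, file.path(dir, "group_network.tsv"),
                  prob = fit$edge_prob)
  invisible(dir)
}

#' Read a draw archive written by [write_draws()]
#'
#' @param dir Archive directory.
#' @return List with `draws` (4-d array), `index` and `diagnostics`.
#' @export
read_draws <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  n <- prod(index$dim)
  con <- file(file.path(dir, "omega.bin"), "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  con <- file(file.path(dir, "diagnostics.bin"), "rb")
  d <- readBin(con, "double", n = sum(unlist(index$diagnostics)), size = 8,
               endian = "little")
  close(con)
  offs <- cumsum(c(0, unlist(index$diagnostics)))
  diags <- stats::setNames(lapply(seq_along(index$diagnostics), function(k) {
    d[(offs[k] + 1):offs[k + 1]]
  }), names(index$diagnostics))
  list(draws = array(x, dim = index$dim), index = index,
       diagnostics = diags)
}

#' Read a sampler configuration from YAML or JSON
#'
#' Every [sampler_config()] field and every hyper-constant of
#' [default_hyperconstants()] can be overridden; unknown keys are an
#' error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [sampler_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  const_keys <- intersect(names(cfg), names(default_hyperconstants()))
  constants <- do.call(default_hyperconstants,
                       cfg[const_keys])
  cfg <- cfg[setdiff(names(cfg), const_keys)]
  do.call(sampler_config, c(cfg, list(constants = constants)))
}
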