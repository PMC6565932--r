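#' RMS error between an estimated network and the truth
#'
#' Root-mean-square error over the `p(p-1)/2` unordered off-diagonal
#' entries.  By default both sides are compared on the partial-correlation
#' scale: `estimated` is taken to be a partial-correlation matrix already,
#' and `truth` (a precision or strength matrix) is normalised to that scale
#' internally.  With `space = "precision"` the two matrices are compared
#' entry for entry as given.
#'
#' @param estimated Estimated matrix (partial correlations by default).
#' @param truth Ground-truth precision/strength matrix.
#' @param space `"pcorr"` (default) or `"precision"`.
#' @return Non-negative scalar.
#' @export
rms_error <- function(estimated, truth, space = c("pcorr", "precision")) {
  space <- match.arg(space)
  if (!all(dim(estimated) == dim(truth))) {
    stop("dimension mismatch between estimate and truth", call. = FALSE)
  }
  if (space == "pcorr") truth <- pcorr_scale(truth)
  rms_offdiag(estimated - truth)
}

#' Normalise RMS errors by the naive-inversion error
#'
#' Expresses each subject's error as a proportion of the error of the
#' unregularised partial-correlation estimate, the anchoring convention of
#' the benchmark: the naive estimator itself scores exactly 1.
#'
#' @param errors Numeric vector of per-subject RMS errors.
#' @param naive_errors Per-subject errors of [naive_partial_correlation()]
#'   on the same subjects.
#' @return Numeric vector of proportions.
#' @export
normalise_rms <- function(errors, naive_errors) {
  if (length(errors) != length(naive_errors)) {
    stop("error vectors must cover the same subjects", call. = FALSE)
  }
  if (any(naive_errors == 0)) {
    stop("naive error of zero; normalisation undefined", call. = FALSE)
  }
  errors / naive_errors
}

#' Area under the edge-recovery ROC curve
#'
#' Scores the ability of inferred connection strengths to identify the true
#' graph: the AUC of the ROC traced as a threshold sweeps over the scores,
#' computed by the rank (Mann-Whitney) statistic with midranks for ties.
#' 1 means some threshold separates present from absent edges perfectly;
#' 0.5 is chance.
#'
#' @param scores Symmetric matrix of edge scores (typically absolute
#'   posterior-mean partial correlations) or a vector over unordered pairs.
#' @param true_graph Symmetric binary adjacency matrix, or binary vector
#'   matching `scores`.
#' @return AUC in `[0, 1]`.
#' @export
edge_roc_auc <- function(scores, true_graph) {
  if (is.matrix(scores)) scores <- scores[upper.tri(scores)]
  if (is.matrix(true_graph)) true_graph <- true_graph[upper.tri(true_graph)]
  if (length(scores) != length(true_graph)) {
    stop("scores and truth must cover the same edges", call. = FALSE)
  }
  lab <- true_graph != 0
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: truth has no edges of one class", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score a set of subject-level network estimates against ground truth
#'
#' Convenience wrapper producing the benchmark's per-subject table: RMS
#' error (partial-correlation space), the naive-inversion error, their
#' ratio, and the edge-recovery AUC of the absolute estimated strengths.
#'
#' @param pcorr_list List of estimated partial-correlation matrices, one
#'   per subject (a single matrix is recycled over subjects).
#' @param truth A `ground_truth` object from [generate_dataset()].
#' @param naive_pcorr Optional list of naive partial-correlation estimates
#'   for the normalisation (ratios are `NA` when absent).
#' @param estimator Label stored in the output.
#' @return Tibble with one row per subject: `estimator`, `subject`, `rms`,
#'   `rms_naive`, `norm_rms`, `auc`.
#' @export
score_estimates <- function(pcorr_list, truth, naive_pcorr = NULL,
                            estimator = "estimate") {
  stopifnot(inherits(truth, "ground_truth"))
  n_sub <- length(truth$omega)
  if (is.matrix(pcorr_list)) pcorr_list <- list(pcorr_list)
  if (length(pcorr_list) == 1 && n_sub > 1) {
    pcorr_list <- rep(pcorr_list, n_sub)
  }
  rms <- vapply(seq_len(n_sub), function(s) {
    rms_error(pcorr_list[[s]], truth$omega[[s]])
  }, numeric(1))
  rms_naive <- if (is.null(naive_pcorr)) {
    rep(NA_real_, n_sub)
  } else {
    vapply(seq_len(n_sub), function(s) {
      rms_error(naive_pcorr[[s]], truth$omega[[s]])
    }, numeric(1))
  }
  auc <- vapply(seq_len(n_sub), function(s) {
    edge_roc_auc(abs(pcorr_list[[s]]), truth$graph)
  }, numeric(1))
  tibble::tibble(
    estimator = estimator,
    subject = seq_len(n_sub),
    rms = rms,
    rms_naive = rms_naive,
    norm_rms = rms / rms_naive,
    auc = auc
  )
}

#' Posterior summaries of a fitted precision model
#'
#' Edge-level summaries of a [run_sampler()] fit: posterior-mean partial
#' correlations for the group and (optionally) each subject, posterior edge
#' inclusion probabilities where the model has indicators, and central
#' credible intervals computed from the stored draw archive when one is
#' present.
#'
#' @param fit A `precision_fit`.
#' @param level Credible level for the intervals (default 0.95).
#' @return List with `group` (tibble: `i`, `j`, `pcorr_mean`, `edge_prob`,
#'   `lower`, `upper`), `subjects` (long tibble with a `subject` column)
#'   and `diagnostics` (one-row tibble).
#' @export
summarise_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "precision_fit"))
  if (fit$n_kept < 1) stop("fit holds no stored draws", call. = FALSE)
  p <- fit$p
  up <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ep <- if (is.null(fit$edge_prob)) rep(NA_real_, nrow(up)) else {
    fit$edge_prob[up]
  }
  lower <- upper <- rep(NA_real_, nrow(up))
  if (!is.null(fit$draws)) {
    alpha <- (1 - level) / 2
    n_kept <- dim(fit$draws)[4]
    n_sub <- dim(fit$draws)[3]
    group_draws <- vapply(seq_len(n_kept), function(k) {
      g <- matrix(0, p, p)
      for (s in seq_len(n_sub)) {
        g <- g + partial_correlation(fit$draws[, , s, k])
      }
      (g / n_sub)[up]
    }, numeric(nrow(up)))
    qs <- apply(group_draws, 1, stats::quantile,
                probs = c(alpha, 1 - alpha))
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  group <- tibble::tibble(
    i = up[, 1], j = up[, 2],
    pcorr_mean = fit$group_pcorr[up],
    edge_prob = ep, lower = lower, upper = upper
  )
  subjects <- dplyr::bind_rows(lapply(seq_len(fit$n_subjects), function(s) {
    tibble::tibble(subject = s, i = up[, 1], j = up[, 2],
                   pcorr_mean = fit$pcorr[[s]][up])
  }))
  diagnostics <- tibble::tibble(
    model = fit$model,
    n_kept = fit$n_kept,
    sigma_accept = fit$sigma_accept,
    pd_failures = fit$pd_failures,
    mean_loglik = mean(fit$loglik)
  )
  list(group = group, subjects = subjects, diagnostics = diagnostics)
}

# standard error of an MCMC mean by batch means
mcse_batch <- function(x, n_batches = 20) {
  n <- length(x)
  n_batches <- min(n_batches, n)
  size <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
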