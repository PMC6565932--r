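#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted precision model into an edge table
#'
#' @param x A `precision_fit`.
#' @param subjects Return one row per subject per edge instead of the
#'   group-level table.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (and node labels when the panel
#'   had them), `estimate` (posterior-mean partial correlation) and
#'   `edge_prob` where available.
#' @export
tidy.precision_fit <- function(x, subjects = FALSE, ...) {
  p <- x$p
  up <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  base <- tibble::tibble(i = up[, 1], j = up[, 2])
  if (!is.null(x$labels)) {
    base$node_i <- x$labels[base$i]
    base$node_j <- x$labels[base$j]
  }
  if (subjects) {
    dplyr::bind_rows(lapply(seq_len(x$n_subjects), function(s) {
      dplyr::mutate(base, subject = s, estimate = x$pcorr[[s]][up],
                    .before = 1)
    }))
  } else {
    base$estimate <- x$group_pcorr[up]
    if (!is.null(x$edge_prob)) base$edge_prob <- x$edge_prob[up]
    base
  }
}

#' One-row summary of a fitted precision model
#'
#' @param x A `precision_fit`.
#' @param ... Unused.
#' @return Tibble: model, dimensions, kept draws, log-likelihood mean,
#'   sigma acceptance rate and the PD-failure count (0 in a healthy run).
#' @export
glance.precision_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    p = x$p,
    n_subjects = x$n_subjects,
    n_kept = x$n_kept,
    mean_loglik = mean(x$loglik),
    sigma_accept = x$sigma_accept,
    pd_failures = x$pd_failures
  )
}

#' Heat-map of the inferred group network
#'
#' @param object A `precision_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the posterior-mean group partial
#'   correlations.
#' @export
autoplot.precision_fit <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$j, y = .data$i,
                                    fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial\ncorrelation",
                  title = paste0("Group network (", object$model, ")")) +
    ggplot2::theme_minimal()
}

#' Bar chart of normalised RMS errors across estimators
#'
#' @param results Tibble from [score_estimates()] (rows from several
#'   estimators may be bound together).
#' @return A ggplot object: mean normalised RMS per estimator with
#'   subject-level standard deviation bars.
#' @export
plot_rms_comparison <- function(results) {
  summ <- dplyr::summarise(
    dplyr::group_by(results, .data$estimator),
    mean_norm_rms = mean(.data$norm_rms),
    sd_norm_rms = stats::sd(.data$norm_rms),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$estimator,
                                     y = .data$mean_norm_rms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_norm_rms - .data$sd_norm_rms,
      ymax = .data$mean_norm_rms + .data$sd_norm_rms), width = 0.2,
      colour = "darkred") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "RMS error / naive inversion error") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
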