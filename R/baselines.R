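#' Unregularised partial-correlation estimates
#'
#' Inverts each subject's sample covariance matrix via its Cholesky
#' factorisation and normalises to partial correlations.  This naive
#' estimator anchors the normalised error metric: every other method's RMS
#' error is reported as a proportion of this one's.
#'
#' @param panel A [ts_panel()] (demeaned internally).
#' @return List with `omega` (list of precision estimates) and `pcorr`
#'   (list of partial-correlation matrices).
#' @export
naive_partial_correlation <- function(panel) {
  panel <- standardise_panel(panel)
  covs <- panel_covariances(panel)
  omega <- lapply(seq_along(covs), function(s) {
    ch <- tryCatch(chol(covs[[s]]), error = function(e) NULL)
    if (is.null(ch)) {
      stop("sample covariance of subject ", s,
           " is singular (n_s < p?); cannot invert", call. = FALSE)
    }
    chol2inv(ch)
  })
  list(omega = omega, pcorr = lapply(omega, partial_correlation))
}

#' Tikhonov-regularised precision estimate
#'
#' `(Sigma + lambda I)^{-1}`: inversion after augmenting the diagonal of the
#' sample covariance.
#'
#' @param sigma Sample covariance matrix.
#' @param lambda Non-negative ridge parameter.
#' @return Symmetric positive-definite precision estimate.
#' @export
tikhonov <- function(sigma, lambda) {
  stopifnot(lambda >= 0)
  chol2inv(chol(sigma + diag(lambda, nrow(sigma))))
}

# mean RMS distance (off-diagonal partial-correlation space) between each
# subject's regularised estimate and the unregularised group average
regularisation_objective <- function(covs, naive_group_pcorr, est_fun) {
  errs <- vapply(covs, function(sig) {
    pc <- partial_correlation(est_fun(sig))
    rms_offdiag(pc - naive_group_pcorr)
  }, numeric(1))
  mean(errs)
}

rms_offdiag <- function(m) {
  sqrt(mean(m[upper.tri(m)]^2))
}

#' Select the Tikhonov ridge parameter
#'
#' Chooses, from a grid, the ridge value minimising the mean RMS distance
#' (over subjects, off-diagonal partial-correlation entries) between the
#' subjects' regularised matrices and their unregularised group-average
#' partial correlation.
#'
#' @param panel A [ts_panel()].
#' @param grid Candidate ridge values (default 30 log-spaced points in
#'   `[1e-4, 1]`).
#' @return List with `lambda` (the argmin) and `objective` (tibble of grid
#'   values and criterion).
#' @export
select_tikhonov_lambda <- function(panel,
                                   grid = 10^seq(-4, 0, length.out = 30)) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  panel <- standardise_panel(panel)
  covs <- panel_covariances(panel)
  naive <- naive_partial_correlation(panel)
  group_pc <- Reduce(`+`, naive$pcorr) / length(naive$pcorr)
  obj <- vapply(grid, function(lam) {
    regularisation_objective(covs, group_pc, function(sig) tikhonov(sig, lam))
  }, numeric(1))
  list(
    lambda = grid[which.min(obj)],
    objective = tibble::tibble(lambda = grid, objective = obj)
  )
}

# penalised log-likelihood: log det(Omega) - tr(Sigma Omega) - lam * ||Omega||_1
glasso_objective <- function(omega, sigma, lam) {
  determinant(omega, logarithm = TRUE)$modulus[1] -
    sum(sigma * omega) - lam * sum(abs(omega))
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Maximises `log det(Omega) - tr(Sigma Omega) - lambda ||Omega||_1` by
#' block coordinate descent over columns, solving each column's lasso
#' subproblem by cyclic soft-thresholding.  The penalty covers all entries
#' of the matrix, including the diagonal.
#'
#' @param sigma Sample covariance matrix (symmetric PSD).
#' @param lambda Non-negative L1 penalty.
#' @param tol Convergence threshold on the maximum elementwise change of the
#'   working covariance (default `1e-6`).
#' @param max_iter Maximum outer cycles (default 500).
#' @return List with `omega` (the estimate), `objective` (value attained),
#'   `iterations` and `converged`.
#' @export
glasso <- function(sigma, lambda, tol = 1e-6, max_iter = 500) {
  stopifnot(lambda >= 0)
  p <- nrow(sigma)
  if (lambda == 0) {
    om <- chol2inv(chol(sigma))
    return(list(omega = om, objective = glasso_objective(om, sigma, 0),
                iterations = 0L, converged = TRUE))
  }
  W <- sigma + diag(lambda, p)
  B <- matrix(0, p - 1, p)  # per-column lasso coefficients
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      keep <- setdiff(seq_len(p), j)
      W11 <- W[keep, keep, drop = FALSE]
      s12 <- sigma[keep, j]
      beta <- B[, j]
      # cyclic coordinate descent on the column lasso
      for (inner in seq_len(200)) {
        delta <- 0
        for (t in seq_len(p - 1)) {
          r <- s12[t] - sum(W11[t, ] * beta) + W11[t, t] * beta[t]
          bt <- sign(r) * max(abs(r) - lambda, 0) / W11[t, t]
          delta <- max(delta, abs(bt - beta[t]))
          beta[t] <- bt
        }
        if (delta < tol) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[keep, j] <- w12
      W[j, keep] <- w12
    }
    if (max(abs(W - W_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("glasso did not converge in ", max_iter, " cycles")
  }
  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    keep <- setdiff(seq_len(p), j)
    o22 <- 1 / (W[j, j] - sum(W[keep, j] * B[, j]))
    omega[j, j] <- o22
    omega[keep, j] <- -B[, j] * o22
  }
  omega <- (omega + t(omega)) / 2
  list(omega = omega, objective = glasso_objective(omega, sigma, lambda),
       iterations = it, converged = converged)
}

#' Select the graphical-lasso penalty
#'
#' Same selection rule as [select_tikhonov_lambda()], with the graphical
#' lasso as the per-subject estimator.
#'
#' @inheritParams select_tikhonov_lambda
#' @return List with `lambda` and `objective`.
#' @export
select_glasso_lambda <- function(panel,
                                 grid = 10^seq(-4, 0, length.out = 30)) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  panel <- standardise_panel(panel)
  covs <- panel_covariances(panel)
  naive <- naive_partial_correlation(panel)
  group_pc <- Reduce(`+`, naive$pcorr) / length(naive$pcorr)
  obj <- vapply(grid, function(lam) {
    regularisation_objective(covs, group_pc,
                             function(sig) glasso(sig, lam)$omega)
  }, numeric(1))
  list(
    lambda = grid[which.min(obj)],
    objective = tibble::tibble(lambda = grid, objective = obj)
  )
}

#' Posterior-mean precision under a Wishart prior
#'
#' With the conjugate prior `Omega ~ W_p(p + 1, I/(p + 1))`, the posterior
#' given a subject's inner products `S` over `n` samples is
#' `W_p(p + 1 + n, ((p + 1) I + S)^{-1})`; this returns its mean
#' `(p + 1 + n) ((p + 1) I + S)^{-1}`.
#'
#' @param S p x p inner-product matrix.
#' @param n Number of samples behind `S`.
#' @return Posterior-mean precision matrix.
#' @export
wishart_posterior_mean <- function(S, n) {
  p <- nrow(S)
  (p + 1 + n) * chol2inv(chol(diag(p + 1, p) + S))
}

#' Gibbs sampler for the hierarchical Wishart model
#'
#' Alternates the exact conditionals of a two-level Wishart hierarchy:
#' subject precisions `Omega_s | B, S_s ~ W_p(nu0 + n_s, (B + S_s)^{-1})`
#' and the group scale `B | {Omega_s} ~ W_p(N nu0 + 3, (I + sum_s
#' Omega_s)^{-1})`, under the weak hyperprior `B ~ W_p(3, I)`.
#'
#' @param ips An [inner_products()] object.
#' @param nu0 Group degrees of freedom (> p - 1).
#' @param n_iter Kept iterations (default 1500).
#' @param n_warmup Warm-up iterations (default 1000).
#' @param fix_B Optional fixed group scale matrix: freezes the `B` update so
#'   the subject draws come straight from their printed conditional (a
#'   testing hook).
#' @param fix_omega Optional fixed list of subject precisions: freezes the
#'   subject updates so the `B` draws come straight from theirs.
#' @return List with `omega_mean` (per-subject posterior means), `pcorr`
#'   (posterior-mean partial correlations, averaged over draws), `B_mean`,
#'   and `nu0`.
#' @export
hier_wishart_gibbs <- function(ips, nu0, n_iter = 1500, n_warmup = 1000,
                               fix_B = NULL, fix_omega = NULL) {
  stopifnot(inherits(ips, "inner_products"))
  p <- ips$p
  if (nu0 <= p - 1) stop("`nu0` must exceed p - 1", call. = FALSE)
  N <- length(ips$S)
  B <- if (is.null(fix_B)) diag(p) else fix_B
  omega <- if (is.null(fix_omega)) {
    lapply(seq_len(N), function(s) diag(p))
  } else {
    fix_omega
  }
  omega_sum <- lapply(seq_len(N), function(s) matrix(0, p, p))
  pcorr_sum <- lapply(seq_len(N), function(s) matrix(0, p, p))
  B_sum <- matrix(0, p, p)
  kept <- 0L
  for (iter in seq_len(n_warmup + n_iter)) {
    if (is.null(fix_omega)) {
      for (s in seq_len(N)) {
        scale_s <- chol2inv(chol(B + ips$S[[s]]))
        omega[[s]] <- stats::rWishart(1, nu0 + ips$n_s[s], scale_s)[, , 1]
      }
    }
    if (is.null(fix_B)) {
      scale_B <- chol2inv(chol(diag(p) + Reduce(`+`, omega)))
      B <- stats::rWishart(1, N * nu0 + 3, scale_B)[, , 1]
    }
    if (iter > n_warmup) {
      kept <- kept + 1L
      for (s in seq_len(N)) {
        omega_sum[[s]] <- omega_sum[[s]] + omega[[s]]
        pcorr_sum[[s]] <- pcorr_sum[[s]] + partial_correlation(omega[[s]])
      }
      B_sum <- B_sum + B
    }
  }
  list(
    omega_mean = lapply(omega_sum, function(m) m / kept),
    pcorr = lapply(pcorr_sum, function(m) m / kept),
    B_mean = B_sum / kept,
    nu0 = nu0
  )
}

#' Select the hierarchical-Wishart group degrees of freedom
#'
#' Empirical selection of `nu0` by bootstrapped cross-validation: over
#' `n_splits` random half-splits of the subjects, fit the hierarchical
#' Wishart model to one half and compare its mean partial correlation to
#' the mean graphical-lasso (`lambda = 0.01`) partial correlation of the
#' other half; the candidate minimising the mean off-diagonal RMS error is
#' returned.
#'
#' @param panel A [ts_panel()] with at least 4 subjects.
#' @param candidates Candidate degrees-of-freedom values.
#' @param n_splits Number of half-splits (default 5).
#' @param n_iter,n_warmup Gibbs run lengths per fit.
#' @return List with `nu0` and `objective` (tibble of candidates and CV
#'   errors).
#' @export
select_nu0 <- function(panel, candidates, n_splits = 5,
                       n_iter = 300, n_warmup = 200) {
  stopifnot(inherits(panel, "ts_panel"))
  N <- length(panel$subjects)
  if (N < 4) stop("need at least 4 subjects to split", call. = FALSE)
  panel <- standardise_panel(panel)
  covs <- panel_covariances(panel)
  glasso_pc <- lapply(covs, function(sig) {
    partial_correlation(glasso(sig, 0.01)$omega)
  })
  splits <- lapply(seq_len(n_splits), function(i) {
    sample(N, floor(N / 2))
  })
  errs <- vapply(candidates, function(nu0) {
    mean(vapply(splits, function(half) {
      ips <- inner_products(ts_panel(panel$subjects[half]))
      fit <- hier_wishart_gibbs(ips, nu0, n_iter, n_warmup)
      hw_mean <- Reduce(`+`, fit$pcorr) / length(fit$pcorr)
      gl <- glasso_pc[-half]
      gl_mean <- Reduce(`+`, gl) / length(gl)
      rms_offdiag(hw_mean - gl_mean)
    }, numeric(1)))
  }, numeric(1))
  list(
    nu0 = candidates[which.min(errs)],
    objective = tibble::tibble(nu0 = candidates, objective = errs)
  )
}
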