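#' Sampler configuration
#'
#' Collects run-length and model options for [run_sampler()].
#'
#' Model variants:
#' \describe{
#'   \item{`strong`}{full hierarchical spike-and-slab prior with shared edge
#'     indicators, learnt sparsity level, group means under a half-Cauchy
#'     scale and log-normal between-subject scales.}
#'   \item{`weak`}{the same hierarchy with the explicit sparsity removed
#'     (all edges included, `a = 1`); sparsity is encouraged only through
#'     shrinkage of the group means towards zero.}
#'   \item{`single_subject`}{simplified variant fitted to the concatenated
#'     panel: zero-centred slab with fixed standard deviation 0.7,
#'     Beta(6, 6) sparsity, no group hierarchy.}
#'   \item{`bayesian_glasso`}{per-subject double-exponential (Laplace) prior
#'     on off-diagonal entries, sampled through its exponential scale
#'     mixture; all edges included.}
#'   \item{`ssvs`}{per-subject two-component normal-mixture
#'     (stochastic-search variable selection) prior with scales `ssvs_v0`,
#'     `ssvs_v1` and mixing weight `ssvs_a`.}
#' }
#'
#' Default run lengths follow the benchmark protocol: 30 000 kept sweeps
#' after 10 000 warm-up for the hierarchical models; 10 000 after 5 000 for
#' the single-subject variant; 3 000 after 1 000 for the per-subject
#' Bayesian-glasso and SSVS chains.
#'
#' @param model One of `"strong"`, `"weak"`, `"single_subject"`,
#'   `"bayesian_glasso"`, `"ssvs"`.
#' @param n_samples,n_warmup Kept and discarded sweep counts (defaults by
#'   model, see above).
#' @param thin Keep every `thin`-th sweep (default 10).
#' @param seed Integer seed controlling all randomness of the run.
#' @param mh_step_logsigma Initial proposal scale of the log-sigma
#'   Metropolis step (adapted towards 40% acceptance during warm-up, then
#'   frozen).
#' @param ssvs_v0,ssvs_v1,ssvs_a SSVS spike/slab scales and mixing weight.
#' @param bglasso_lambda Laplace rate of the Bayesian graphical lasso.
#' @param store_draws Keep thinned precision draws (`NA`: store when the
#'   archive stays below ~100 MB).
#' @param fix_z Optional: freeze the edge indicators of the strong model at
#'   their initial value (`TRUE` freezes the full graph).
#' @param constants Hyper-constants, see [default_hyperconstants()].
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(model = c("strong", "weak", "single_subject",
                                     "bayesian_glasso", "ssvs"),
                           n_samples = NULL, n_warmup = NULL, thin = 10,
                           seed = 1L, mh_step_logsigma = 0.1,
                           ssvs_v0 = 0.05, ssvs_v1 = 2.5, ssvs_a = 0.5,
                           bglasso_lambda = 1, store_draws = NA,
                           fix_z = FALSE,
                           constants = default_hyperconstants()) {
  model <- match.arg(model)
  defaults <- switch(model,
    strong = c(30000L, 10000L),
    weak = c(30000L, 10000L),
    single_subject = c(10000L, 5000L),
    c(3000L, 1000L)
  )
  if (is.null(n_samples)) n_samples <- defaults[1]
  if (is.null(n_warmup)) n_warmup <- defaults[2]
  stopifnot(n_samples >= 0, n_warmup >= 0, thin >= 1,
            mh_step_logsigma > 0, ssvs_v0 > 0, ssvs_v1 > 0,
            ssvs_a > 0, ssvs_a <= 1, bglasso_lambda > 0)
  structure(
    list(model = model, n_samples = as.integer(n_samples),
         n_warmup = as.integer(n_warmup), thin = as.integer(thin),
         seed = as.integer(seed), mh_step_logsigma = mh_step_logsigma,
         ssvs_v0 = ssvs_v0, ssvs_v1 = ssvs_v1, ssvs_a = ssvs_a,
         bglasso_lambda = bglasso_lambda, store_draws = store_draws,
         fix_z = isTRUE(fix_z), constants = constants),
    class = "sampler_config"
  )
}

#' Initial sampler state for a panel
#'
#' Warm start inside the positive-definite cone: per-subject precisions from
#' Tikhonov-regularised inversion (`lambda = 0.01`); edge indicators from
#' thresholding the group-mean absolute partial correlation at 0.05; group
#' means from the group-mean precision; sigma at `m_sigma`; `chi` at `A`;
#' `a` at 0.5; diagonal rates at their conditional mean.
#'
#' @param panel Standardised [ts_panel()].
#' @param constants Hyper-constants.
#' @param full_graph Start with every edge included (used by the weak model
#'   and frozen-graph runs).
#' @return List holding the full sampler state.
#' @export
initial_state <- function(panel, constants = default_hyperconstants(),
                          full_graph = FALSE) {
  covs <- panel_covariances(panel)
  p <- panel$p
  omega <- lapply(covs, function(sig) tikhonov(sig, 0.01))
  pc <- lapply(omega, partial_correlation)
  group_pc <- Reduce(`+`, pc) / length(pc)
  Z <- if (full_graph) {
    matrix(1L, p, p)
  } else {
    (abs(group_pc) > 0.05) * 1L
  }
  diag(Z) <- 0L
  mu <- Reduce(`+`, omega) / length(omega)
  diag(mu) <- 0
  sigma <- matrix(constants$m_sigma, p, p)
  lambda_s <- vapply(omega, function(o) {
    (constants$gamma_shape + p) / (sum(diag(o)) / 2)
  }, numeric(1))
  S <- lapply(panel$subjects, tcrossprod)
  list(
    Omega = omega, S = S, n_s = panel$n_s, p = p,
    mu = mu, sigma = sigma, Z = Z,
    chi = constants$A, xi = 1, a = 0.5, lambda_s = lambda_s,
    constants = constants, mh_step = 0.1
  )
}

# collapsed posterior of the included group means of one column:
# returns the Cholesky factor of the precision M and the linear term m
column_mu_posterior <- function(upsilon_list, s12_list, inc, sigma12, chi) {
  k <- length(inc)
  d <- sigma12[inc]^2
  dinv <- 1 / d
  M <- diag(dinv * length(upsilon_list), k) + diag(1 / chi^2, k)
  m <- numeric(k)
  for (s in seq_along(upsilon_list)) {
    b <- -s12_list[[s]][inc]
    Q <- upsilon_list[[s]][inc, inc, drop = FALSE]
    diag(Q) <- diag(Q) + dinv
    ch <- chol(Q)
    Qinv_b <- backsolve(ch, forwardsolve(t(ch), b))
    Qinv_Dinv <- backsolve(ch, forwardsolve(t(ch), diag(dinv, k)))
    M <- M - dinv * Qinv_Dinv
    m <- m + dinv * Qinv_b
  }
  M <- (M + t(M)) / 2
  list(chol_M = chol(M), m = m)
}

#' One full Gibbs sweep (reference implementation)
#'
#' Visits every column of the precision matrices in random order; for each
#' column it partitions all subjects, (strong model) updates the edge
#' indicators by collapsed Metropolis-Hastings, draws the group means of
#' the column from their collapsed conditional, then draws every subject's
#' strengths and Schur complement and reassembles the column.  Global
#' updates of the between-subject scales, the global scale, the sparsity
#' level and the diagonal rates follow.  This R implementation mirrors the
#' compiled engine used by [run_sampler()] and is intended for testing and
#' small problems.
#'
#' @param state Sampler state from [initial_state()].
#' @param model `"strong"` or `"weak"`.
#' @param update_z Whether to move the edge indicators (ignored for
#'   `"weak"`).
#' @return Updated state.
#' @export
gibbs_sweep <- function(state, model = c("strong", "weak"),
                        update_z = TRUE) {
  model <- match.arg(model)
  p <- state$p
  n_sub <- length(state$Omega)
  if (model == "weak") {
    state$Z <- matrix(1L, p, p); diag(state$Z) <- 0L
    state$a <- 1
  }
  for (j in sample.int(p)) {
    keep <- setdiff(seq_len(p), j)
    ups <- vector("list", n_sub)
    s12 <- vector("list", n_sub)
    o11inv <- vector("list", n_sub)
    scale22 <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      part <- partition_column(state$Omega[[s]], state$S[[s]], j)
      o11inv[[s]] <- chol2inv(chol(part$omega11))
      scale22[s] <- part$s22 + state$lambda_s[s]
      ups[[s]] <- compute_upsilon(part$s22, state$lambda_s[s], o11inv[[s]])
      s12[[s]] <- part$s12
    }
    sigma12 <- state$sigma[keep, j]
    z12 <- state$Z[keep, j]
    if (model == "strong" && update_z) {
      z12 <- update_z_column(ups, s12, z12, sigma12, state$chi, state$a)
      state$Z[keep, j] <- z12
      state$Z[j, keep] <- z12
    }
    mu12 <- stats::rnorm(p - 1, 0, state$chi)
    inc <- which(z12 == 1)
    if (length(inc)) {
      post <- column_mu_posterior(ups, s12, inc, sigma12, state$chi)
      mean_mu <- backsolve(post$chol_M,
                           forwardsolve(t(post$chol_M), post$m))
      mu12[inc] <- mean_mu +
        backsolve(post$chol_M, stats::rnorm(length(inc)))
    }
    state$mu[keep, j] <- mu12
    state$mu[j, keep] <- mu12
    for (s in seq_len(n_sub)) {
      u <- draw_column_strengths(ups[[s]], s12[[s]], mu12, sigma12, z12)
      nu <- draw_nu(state$n_s[s], scale22[s] - state$lambda_s[s],
                    state$lambda_s[s])
      o22 <- nu + drop(crossprod(u, o11inv[[s]] %*% u))
      state$Omega[[s]][keep, j] <- u
      state$Omega[[s]][j, keep] <- u
      state$Omega[[s]][j, j] <- o22
    }
  }
  # global updates over unordered pairs
  up <- which(upper.tri(state$mu), arr.ind = TRUE)
  u_mat <- vapply(seq_len(nrow(up)), function(e) {
    vapply(state$Omega, function(o) o[up[e, 1], up[e, 2]], numeric(1))
  }, numeric(n_sub))
  if (n_sub == 1) u_mat <- matrix(u_mat, nrow = 1)
  mu_up <- state$mu[upper.tri(state$mu)]
  z_up <- state$Z[upper.tri(state$Z)]
  sig <- update_sigma(u_mat, mu_up, z_up,
                      state$sigma[upper.tri(state$sigma)],
                      state$constants, state$mh_step)
  state$sigma[upper.tri(state$sigma)] <- sig$sigma12
  state$sigma[lower.tri(state$sigma)] <- t(state$sigma)[lower.tri(state$sigma)]
  cx <- update_chi(mu_up, state$xi, state$constants$A)
  state$chi <- cx$chi
  state$xi <- cx$xi
  if (model == "strong") state$a <- update_a(state$Z, state$constants)
  state$lambda_s <- vapply(state$Omega, function(o) {
    update_lambda(diag(o), state$constants)
  }, numeric(1))
  state
}

#' Fit a hierarchical precision model by MCMC
#'
#' Runs the block-Gibbs / collapsed Metropolis-Hastings sampler for the
#' selected model on a panel of time series.  The panel is temporally
#' demeaned first; every stored precision draw is symmetric positive
#' definite by construction of the column updates.
#'
#' The `single_subject` model is fitted to the concatenation of all
#' subjects; `bayesian_glasso` and `ssvs` fit an independent chain per
#' subject.  The hierarchical `strong` and `weak` models fit all subjects
#' jointly.
#'
#' @param panel A [ts_panel()].
#' @param config A [sampler_config()].
#' @return Object of class `precision_fit` with posterior-mean partial
#'   correlations per subject (`pcorr`), the group-level mean
#'   (`group_pcorr`), posterior-mean precisions (`omega_mean`), per-edge
#'   inclusion probabilities (`edge_prob`, where the model has indicators),
#'   thinned diagnostics (`chi`, `a`, `loglik` series, sigma acceptance
#'   rate) and, optionally, the thinned precision draw archive (`draws`,
#'   a p x p x subjects x draws array).
#' @export
run_sampler <- function(panel, config = sampler_config()) {
  stopifnot(inherits(panel, "ts_panel"), inherits(config, "sampler_config"))
  panel <- standardise_panel(panel)
  if (any(!is.finite(unlist(lapply(panel$subjects, range))))) {
    stop("panel contains non-finite values", call. = FALSE)
  }
  if (panel$p > sum(panel$n_s)) {
    warning("more nodes than total time points; estimates rely on the prior")
  }
  set.seed(config$seed)
  model <- config$model
  if (model == "single_subject") {
    fit_panel <- concatenate_panel(panel)
  } else {
    fit_panel <- panel
  }
  n_sub <- length(fit_panel$subjects)
  p <- fit_panel$p
  store <- config$store_draws
  n_kept <- config$n_samples %/% config$thin
  if (is.na(store)) {
    store <- (as.numeric(p)^2 * n_sub * n_kept * 8) < 1e8
  }
  if (model %in% c("bayesian_glasso", "ssvs")) {
    fits <- lapply(seq_len(n_sub), function(s) {
      sub_panel <- ts_panel(fit_panel$subjects[s])
      run_chain_once(sub_panel, config, store)
    })
    out <- combine_subject_chains(fits, panel, config, store)
  } else {
    out <- run_chain_once(fit_panel, config, store)
    out <- finalise_fit(out, panel, config, store)
  }
  out
}

# run the compiled engine on one (possibly single-subject) panel
run_chain_once <- function(panel, config, store) {
  st <- initial_state(panel, config$constants,
                      full_graph = config$model != "strong" || config$fix_z)
  model_code <- match(config$model,
                      c("strong", "weak", "single_subject",
                        "bayesian_glasso", "ssvs")) - 1L
  S_cube <- array(0, c(panel$p, panel$p, length(panel$subjects)))
  Om_cube <- array(0, dim(S_cube))
  for (s in seq_along(panel$subjects)) {
    S_cube[, , s] <- st$S[[s]]
    Om_cube[, , s] <- st$Omega[[s]]
  }
  hp_run_chain(
    S_cube, as.integer(panel$n_s), model_code, Om_cube,
    st$mu, st$sigma, st$Z, st$chi, st$a, st$lambda_s,
    config$constants, config$n_warmup, config$n_samples, config$thin,
    config$mh_step_logsigma, config$fix_z,
    config$ssvs_v0, config$ssvs_v1, config$ssvs_a,
    config$bglasso_lambda, store
  )
}

cube_to_list <- function(a) {
  lapply(seq_len(dim(a)[3]), function(s) a[, , s])
}

finalise_fit <- function(raw, panel, config, store) {
  structure(
    list(
      model = config$model, config = config,
      p = dim(raw$pcorr_mean)[1],
      n_subjects = dim(raw$pcorr_mean)[3],
      n_s = panel$n_s, labels = panel$labels,
      pcorr = cube_to_list(raw$pcorr_mean),
      group_pcorr = raw$group_pcorr_mean,
      omega_mean = cube_to_list(raw$omega_mean),
      edge_prob = if (config$model %in% c("strong", "single_subject",
                                          "ssvs")) raw$edge_prob else NULL,
      chi = if (length(raw$chi_draws)) raw$chi_draws else NULL,
      a = if (length(raw$a_draws)) raw$a_draws else NULL,
      loglik = raw$loglik_draws,
      sigma_accept = raw$sigma_accept,
      mh_step = raw$mh_step,
      pd_failures = raw$pd_failures,
      n_kept = raw$n_kept,
      draws = if (store) raw$omega_draws else NULL
    ),
    class = "precision_fit"
  )
}

combine_subject_chains <- function(fits, panel, config, store) {
  n_sub <- length(fits)
  p <- dim(fits[[1]]$pcorr_mean)[1]
  pcorr <- lapply(fits, function(f) f$pcorr_mean[, , 1])
  omega_mean <- lapply(fits, function(f) f$omega_mean[, , 1])
  edge_prob <- if (config$model == "ssvs") {
    Reduce(`+`, lapply(fits, function(f) f$edge_prob)) / n_sub
  } else {
    NULL
  }
  draws <- NULL
  if (store) {
    n_kept <- fits[[1]]$n_kept
    draws <- array(0, c(p, p, n_sub, n_kept))
    for (s in seq_len(n_sub)) draws[, , s, ] <- fits[[s]]$omega_draws[, , 1, ]
  }
  structure(
    list(
      model = config$model, config = config, p = p, n_subjects = n_sub,
      n_s = panel$n_s, labels = panel$labels,
      pcorr = pcorr,
      group_pcorr = Reduce(`+`, pcorr) / n_sub,
      omega_mean = omega_mean,
      edge_prob = edge_prob,
      chi = NULL, a = NULL,
      loglik = Reduce(`+`, lapply(fits, function(f) f$loglik_draws)),
      sigma_accept = NA_real_,
      mh_step = NA_real_,
      pd_failures = sum(vapply(fits, function(f) f$pd_failures, numeric(1))),
      n_kept = fits[[1]]$n_kept,
      draws = draws
    ),
    class = "precision_fit"
  )
}

#' @export
print.precision_fit <- function(x, ...) {
  cat("<precision_fit> model = ", x$model, ", p = ", x$p,
      ", subjects = ", x$n_subjects, ", kept draws = ", x$n_kept, "\n",
      sep = "")
  if (!is.null(x$edge_prob)) {
    cat("  mean posterior edge probability: ",
        round(mean(x$edge_prob[upper.tri(x$edge_prob)]), 3), "\n", sep = "")
  }
  cat("  PD failures during sampling: ", x$pd_failures, "\n", sep = "")
  invisible(x)
}
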