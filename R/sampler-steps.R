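#' Gibbs draw of the Schur complement of a column
#'
#' The Schur complement `nu_s` of a precision-matrix column has the exact
#' conditional `Gamma(shape = n_s/2 + 1, rate = (s22 + lambda_s)/2)` under
#' the Gaussian likelihood and exponential diagonal prior.  Strict
#' positivity of this draw is what guarantees positive definiteness of the
#' reassembled matrix.
#'
#' @param n_s Number of time points for the subject.
#' @param s22 Diagonal inner-product entry of the column.
#' @param lambda_s Subject's diagonal rate (positive).
#' @param n Number of draws (default 1).
#' @return Positive draw(s).
#' @export
draw_nu <- function(n_s, s22, lambda_s, n = 1) {
  rate <- (s22 + lambda_s) / 2
  if (rate <= 0) stop("`s22 + lambda_s` must be positive", call. = FALSE)
  stats::rgamma(n, shape = n_s / 2 + 1, rate = rate)
}

#' Column regression precision matrix
#'
#' The quadratic-form matrix of the column conditional,
#' `Upsilon_s = (s22 + lambda_s) * omega11_inv`, playing the role of `X'X`
#' in the linked-regression view of a precision column.
#'
#' @param s22 Diagonal inner-product entry.
#' @param lambda_s Subject's diagonal rate.
#' @param omega11_inv Inverse of the principal minor (symmetric PD).
#' @return Symmetric positive-definite matrix.
#' @export
compute_upsilon <- function(s22, lambda_s, omega11_inv) {
  (s22 + lambda_s) * omega11_inv
}

#' Gibbs draw of a column of edge strengths for one subject
#'
#' Conditional on the spike-and-slab pattern `z12`, entries with `z = 0`
#' are exactly zero; the included subvector is drawn from the Gaussian with
#' precision `Q = Upsilon[in, in] + diag(1/sigma12^2)` and mean
#' `Q^{-1} (-s12[in] + mu12[in]/sigma12[in]^2)`.
#'
#' @param upsilon Column regression precision ([compute_upsilon()]).
#' @param s12 Off-diagonal inner products of the column.
#' @param mu12 Slab means for the column's edges.
#' @param sigma12 Slab standard deviations (positive).
#' @param z12 Binary inclusion vector.
#' @return Numeric vector `u` of length p-1.
#' @export
draw_column_strengths <- function(upsilon, s12, mu12, sigma12, z12) {
  stopifnot(all(z12 %in% c(0, 1)), all(sigma12 > 0))
  u <- numeric(length(s12))
  inc <- which(z12 == 1)
  if (length(inc)) {
    dinv <- 1 / sigma12[inc]^2
    Q <- upsilon[inc, inc, drop = FALSE]
    diag(Q) <- diag(Q) + dinv
    ch <- chol(Q)
    mean_u <- backsolve(ch, forwardsolve(t(ch), -s12[inc] + mu12[inc] * dinv))
    u[inc] <- mean_u + backsolve(ch, stats::rnorm(length(inc)))
  }
  u
}

#' Collapsed log-evidence of a column's data under an edge pattern
#'
#' Integrates the column's Gaussian likelihood factors analytically over the
#' subject-level strengths `u_s` and the group means `mu12` of the included
#' edges, conditional on the inclusion pattern `z12`, the slab scales
#' `sigma12` and the global scale `chi`.  Both layers are Gaussian, so the
#' integral is available in closed form.  The value is reported up to an
#' additive constant that does not depend on `z12`; only differences between
#' patterns are meaningful, and those differences drive the
#' Metropolis-Hastings updates of the network structure.
#'
#' @param upsilon_list List (one per subject) of column regression
#'   precisions.
#' @param s12_list List (one per subject) of off-diagonal inner products.
#' @param z12 Binary inclusion vector.
#' @param sigma12 Slab standard deviations.
#' @param chi Global scale of the group means.
#' @return Scalar log evidence (up to a shared constant; 0 for the empty
#'   pattern).
#' @export
column_log_evidence <- function(upsilon_list, s12_list, z12, sigma12, chi) {
  inc <- which(z12 == 1)
  k <- length(inc)
  if (k == 0) return(0)
  d <- sigma12[inc]^2
  dinv <- 1 / d
  M <- diag(dinv * length(upsilon_list), k) + diag(1 / chi^2, k)
  m <- numeric(k)
  tot <- 0
  for (s in seq_along(upsilon_list)) {
    b <- -s12_list[[s]][inc]
    Q <- upsilon_list[[s]][inc, inc, drop = FALSE]
    diag(Q) <- diag(Q) + dinv
    ch <- chol(Q)
    Qinv_b <- backsolve(ch, forwardsolve(t(ch), b))
    tot <- tot - 0.5 * sum(log(d)) - sum(log(diag(ch))) +
      0.5 * sum(b * Qinv_b)
    Qinv_Dinv <- backsolve(ch, forwardsolve(t(ch), diag(dinv, k)))
    M <- M - dinv * Qinv_Dinv  # D^{-1} Q^{-1} D^{-1} with diagonal D
    m <- m + dinv * Qinv_b
  }
  M <- (M + t(M)) / 2
  chM <- chol(M)
  Minv_m <- backsolve(chM, forwardsolve(t(chM), m))
  tot - 0.5 * k * log(chi^2) - sum(log(diag(chM))) + 0.5 * sum(m * Minv_m)
}

#' Metropolis-Hastings sweep over a column's edge indicators
#'
#' Visits every entry of `z12` once, in random order, proposing a
#' single-entry flip and accepting with probability
#' `min(1, exp(delta log evidence) * prior ratio)`, where the prior ratio is
#' `a/(1-a)` for an addition and its inverse for a removal.  The continuous
#' strengths and group means are integrated out via
#' [column_log_evidence()], which is what makes these discrete moves mix.
#'
#' @inheritParams column_log_evidence
#' @param a Current sparsity level in (0, 1].
#' @return Updated binary vector `z12`.
#' @export
update_z_column <- function(upsilon_list, s12_list, z12, sigma12, chi, a) {
  ev <- column_log_evidence(upsilon_list, s12_list, z12, sigma12, chi)
  for (t in sample.int(length(z12))) {
    if (a >= 1 && z12[t] == 1) next  # removal has zero prior mass
    zprop <- z12
    zprop[t] <- 1 - zprop[t]
    evp <- column_log_evidence(upsilon_list, s12_list, zprop, sigma12, chi)
    lpr <- if (zprop[t] == 1) log(a) - log1p(-a) else log1p(-a) - log(a)
    if (log(stats::runif(1)) < evp - ev + lpr) {
      z12 <- zprop
      ev <- evp
    }
  }
  z12
}

#' Gibbs draw of the group-mean strengths of a column
#'
#' For included edges the conditional given the subject strengths is the
#' conjugate normal with precision `N/sigma^2 + 1/chi^2` and mean
#' `(sum_s u_s / sigma^2) / precision`.  Excluded edges refresh from the
#' prior `N(0, chi^2)`, keeping the chain on the full parameter space.
#'
#' @param u_mat Matrix of subject strengths, subjects in rows, the column's
#'   edges in columns.
#' @param sigma12 Slab standard deviations per edge.
#' @param chi Global scale.
#' @param z12 Binary inclusion vector.
#' @return Numeric vector of group means, one per edge.
#' @export
update_mu_column <- function(u_mat, sigma12, chi, z12) {
  n_sub <- nrow(u_mat)
  k <- ncol(u_mat)
  prec <- n_sub / sigma12^2 + 1 / chi^2
  mean_mu <- colSums(u_mat) / sigma12^2 / prec
  mu <- stats::rnorm(k, mean_mu, 1 / sqrt(prec))
  mu[z12 == 0] <- stats::rnorm(sum(z12 == 0), 0, chi)
  mu
}

#' Random-walk update of the between-subject edge scales
#'
#' For each included edge, a Metropolis step on `log sigma_ij` with a
#' Gaussian proposal of scale `step`; the target is the log-normal prior
#' `log sigma ~ N(log m_sigma, s_sigma^2)` times the slab likelihood of the
#' subject strengths.  Excluded edges refresh directly from the prior.
#'
#' @param u_mat Matrix of subject strengths (subjects x edges).
#' @param mu12 Group means per edge.
#' @param z12 Binary inclusion vector.
#' @param sigma12 Current standard deviations.
#' @param constants A [default_hyperconstants()] object.
#' @param step Proposal scale on the log scale.
#' @return List with `sigma12` and the acceptance indicator vector
#'   `accepted` (NA for refreshed edges).
#' @export
update_sigma <- function(u_mat, mu12, z12, sigma12,
                         constants = default_hyperconstants(), step = 0.1) {
  k <- length(sigma12)
  accepted <- rep(NA, k)
  for (t in seq_len(k)) {
    if (z12[t] == 0) {
      sigma12[t] <- stats::rlnorm(1, log(constants$m_sigma),
                                  constants$s_sigma)
      next
    }
    ls <- log(sigma12[t])
    lsp <- ls + step * stats::rnorm(1)
    logpost <- function(l) {
      stats::dnorm(l, log(constants$m_sigma), constants$s_sigma, log = TRUE) +
        sum(stats::dnorm(u_mat[, t], mu12[t], exp(l), log = TRUE))
    }
    acc <- log(stats::runif(1)) < logpost(lsp) - logpost(ls)
    accepted[t] <- acc
    if (acc) sigma12[t] <- exp(lsp)
  }
  list(sigma12 = sigma12, accepted = accepted)
}

#' Gibbs update of the global mean-strength scale
#'
#' Uses the inverse-gamma scale-mixture expansion of the half-Cauchy prior:
#' `chi^2 | xi, mu ~ IG((E + 1)/2, 1/xi + sum(mu^2)/2)` over the `E` edge
#' means, and `xi | chi^2 ~ IG(1, 1/A^2 + 1/chi^2)`.  Alternating the two
#' draws with the means refreshed from their prior leaves the half-Cauchy
#' marginal on `chi` invariant.
#'
#' @param mu Vector of group means over all unordered node pairs.
#' @param xi Current auxiliary scale.
#' @param A Half-Cauchy scale.
#' @return List with `chi` and `xi`.
#' @export
update_chi <- function(mu, xi, A) {
  E <- length(mu)
  chi2 <- rinvgamma1((E + 1) / 2, 1 / xi + sum(mu^2) / 2)
  xi <- rinvgamma1(1, 1 / A^2 + 1 / chi2)
  list(chi = sqrt(chi2), xi = xi)
}

#' Gibbs update of the network sparsity level
#'
#' Beta-Bernoulli conjugacy over the `E = p(p-1)/2` unordered pairs:
#' `a | Z ~ Beta(a_pi + #edges, b_pi + #non-edges)`.
#'
#' @param Z Symmetric binary adjacency matrix (diagonal ignored).
#' @param constants A [default_hyperconstants()] object.
#' @return Draw of `a` in (0, 1).
#' @export
update_a <- function(Z, constants = default_hyperconstants()) {
  up <- upper.tri(Z)
  on <- sum(Z[up] == 1)
  off <- sum(up) - on
  stats::rbeta(1, constants$a_pi + on, constants$b_pi + off)
}

#' Gibbs update of a subject's diagonal rate
#'
#' Conjugate update of the exponential-prior rate under the neutral Gamma
#' hyperprior (shape 1/3, rate 0):
#' `lambda_s | diag ~ Gamma(1/3 + p, sum(omega_ii)/2)`.
#'
#' @param diag_omega Positive diagonal entries of the subject's precision.
#' @param constants A [default_hyperconstants()] object.
#' @return Positive draw of `lambda_s`.
#' @export
update_lambda <- function(diag_omega, constants = default_hyperconstants()) {
  if (any(diag_omega <= 0)) {
    stop("diagonal entries must be positive", call. = FALSE)
  }
  stats::rgamma(1, shape = constants$gamma_shape + length(diag_omega),
                rate = sum(diag_omega) / 2)
}
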