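#' Default hyper-parameter constants for the hierarchical prior
#'
#' Returns the fixed constants of the hierarchical spike-and-slab prior:
#' the log-normal prior on between-subject edge scales is centred on
#' `m_sigma` with log-scale standard deviation `s_sigma`; the half-Cauchy
#' prior on the global mean-strength scale has scale `A` (appropriate for
#' variance-scaled data where partial correlations rarely exceed 0.7); the
#' Beta prior on the network sparsity level has parameters `a_pi`, `b_pi`
#' (6, 6 places most prior mass between 0.3 and 0.7); and the neutral Gamma
#' hyperprior on the diagonal rates has shape `gamma_shape = 1/3` with rate
#' zero (improper, used only through its conjugate update).
#'
#' @param ... Named overrides of individual constants.
#' @return Object of class `hyper_constants` (a named list).
#' @export
default_hyperconstants <- function(...) {
  h <- list(
    m_sigma = 0.5,
    s_sigma = 1,
    A = 0.7,
    a_pi = 6,
    b_pi = 6,
    gamma_shape = 1 / 3
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(h))
    if (length(bad)) stop("unknown hyper-constant(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    h[names(dots)] <- dots
  }
  if (any(unlist(h) <= 0)) stop("all hyper-constants must be positive",
                                call. = FALSE)
  structure(h, class = "hyper_constants")
}

#' Log-density of the slab on an included edge
#'
#' The slab of the spike-and-slab prior on an included off-diagonal
#' precision entry is a normal distribution centred on the group-mean
#' strength `mu_ij` with between-subject standard deviation `sigma_ij`.
#'
#' @param omega Precision entry (or vector of entries) to evaluate.
#' @param mu_ij Group mean strength.
#' @param sigma_ij Between-subject standard deviation (positive).
#' @return Log normal density at `omega`.
#' @export
log_slab_density <- function(omega, mu_ij, sigma_ij) {
  if (any(sigma_ij <= 0)) stop("`sigma_ij` must be positive", call. = FALSE)
  stats::dnorm(omega, mean = mu_ij, sd = sigma_ij, log = TRUE)
}

#' Draw from the half-Cauchy distribution C+(0, scale)
#'
#' @param n Number of draws.
#' @param scale Scale parameter.
#' @return Positive draws.
#' @export
rhalfcauchy <- function(n, scale) {
  abs(stats::rcauchy(n, location = 0, scale = scale))
}

#' Half-Cauchy cumulative distribution function
#'
#' @param q Quantiles.
#' @param scale Scale parameter.
#' @return `P(X <= q)` for `X ~ C+(0, scale)`.
#' @export
phalfcauchy <- function(q, scale) {
  ifelse(q < 0, 0, 2 / pi * atan(q / scale))
}

# Scale-mixture expansion of the half-Cauchy prior on chi:
#   chi^2 | xi ~ Inverse-Gamma(1/2, 1/xi),  xi ~ Inverse-Gamma(1/2, 1/A^2)
# marginalises to chi ~ C+(0, A).  Inverse-Gamma(shape, scale) draws are
# 1 / rgamma(shape, rate = scale).
rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1, shape, rate = scale)

#' One ancestral draw from the full hierarchical prior
#'
#' Draws the hierarchy top-down: sparsity `a ~ Beta(a_pi, b_pi)`, global
#' scale `chi ~ C+(0, A)`, per-edge indicators `z_ij ~ Bernoulli(a)`, means
#' `mu_ij ~ N(0, chi^2)`, log-normal scales `sigma_ij`, diagonal rates
#' `lambda_s` (drawn from an exponential stand-in since the neutral Gamma
#' prior is improper), then per-subject precision entries from the slab or
#' spike.  Raw subject matrices need not be positive definite; they are
#' repaired with [nearest_pd()] so the returned set lies in the PD cone.
#'
#' @param p Node count (>= 2).
#' @param n_subjects Number of subjects.
#' @param constants A [default_hyperconstants()] object.
#' @param a Optional fixed sparsity level overriding the Beta draw (used to
#'   force pure-spike or full models).
#' @return List with `params` (list: `mu`, `sigma`, `chi`, `a`, `Z`,
#'   `lambda_s`) and `omega` (list of PD precision matrices).
#' @export
sample_prior_predictive <- function(p, n_subjects,
                                    constants = default_hyperconstants(),
                                    a = NULL) {
  stopifnot(p >= 2, n_subjects >= 1)
  if (is.null(a)) a <- stats::rbeta(1, constants$a_pi, constants$b_pi)
  chi <- rhalfcauchy(1, constants$A)
  E <- p * (p - 1) / 2
  up <- upper.tri(matrix(0, p, p))
  Z <- matrix(0L, p, p)
  Z[up] <- stats::rbinom(E, 1, a)
  Z <- Z + t(Z)
  mu <- matrix(0, p, p)
  mu[up] <- stats::rnorm(E, 0, chi)
  mu <- mu + t(mu)
  sigma <- matrix(0, p, p)
  sigma[up] <- stats::rlnorm(E, log(constants$m_sigma), constants$s_sigma)
  sigma <- sigma + t(sigma)
  lambda_s <- stats::rexp(n_subjects, 1)
  omega <- lapply(seq_len(n_subjects), function(s) {
    o <- matrix(0, p, p)
    o[up] <- ifelse(Z[up] == 1, stats::rnorm(E, mu[up], sigma[up]), 0)
    o <- o + t(o)
    diag(o) <- stats::rexp(p, lambda_s[s] / 2)
    if (!is_positive_definite(o)) o <- nearest_pd(o, 1e-4)
    o
  })
  list(
    params = list(mu = mu, sigma = sigma, chi = chi, a = a, Z = Z,
                  lambda_s = lambda_s),
    omega = omega
  )
}
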