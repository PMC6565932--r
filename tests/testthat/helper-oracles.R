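# Independent numerical oracles used by the tests.  These deliberately avoid
# the package's own algebra: quadrature works on the raw integrands, and the
# convex solver is a separate ADMM route to the graphical-lasso optimum.

# Gauss-Hermite nodes/weights (weight exp(-t^2)) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Numerical column evidence: integrates the raw column integrand
#   prod_s  int exp(-u' Ups_s u / 2 - s12_s' u) N(u; mu, diag(sigma^2)) du
# over mu ~ N(0, chi^2 I), by Gauss-Hermite product rules centred on the
# Gaussian factors.  Supports inclusion patterns with 0, 1 or 2 edges.
oracle_column_evidence <- function(ups_list, s12_list, z12, sigma12, chi,
                                   n_nodes = 100) {
  inc <- which(z12 == 1)
  k <- length(inc)
  if (k == 0) return(0)
  gh <- gauss_hermite(n_nodes)
  tn <- gh$nodes
  tw <- gh$weights / sqrt(pi)  # weights for N(0, 1/2)-style expectation
  sig <- sigma12[inc]
  inner <- function(mu_vec) {
    # expectation over u ~ N(mu, diag(sig^2)) of exp(-u'Au/2 - b'u)
    val <- 1
    for (s in seq_along(ups_list)) {
      A <- ups_list[[s]][inc, inc, drop = FALSE]
      b <- s12_list[[s]][inc]
      if (k == 1) {
        u <- mu_vec + sqrt(2) * sig * tn
        val <- val * sum(tw * exp(-0.5 * A[1, 1] * u^2 - b[1] * u))
      } else {
        u1 <- mu_vec[1] + sqrt(2) * sig[1] * tn
        u2 <- mu_vec[2] + sqrt(2) * sig[2] * tn
        g1 <- outer(u1, u2, function(x, y) {
          exp(-0.5 * (A[1, 1] * x^2 + 2 * A[1, 2] * x * y + A[2, 2] * y^2) -
                b[1] * x - b[2] * y)
        })
        val <- val * drop(tw %*% g1 %*% tw)
      }
    }
    val
  }
  if (k == 1) {
    mu_nodes <- sqrt(2) * chi * tn
    total <- sum(tw * vapply(mu_nodes, inner, numeric(1)))
  } else {
    mu1 <- sqrt(2) * chi * tn
    mu2 <- sqrt(2) * chi * tn
    g <- matrix(0, n_nodes, n_nodes)
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        g[i, j] <- inner(c(mu1[i], mu2[j]))
      }
    }
    total <- drop(tw %*% g %*% tw)
  }
  log(total)
}

# ADMM route to the graphical lasso optimum (penalty on all entries),
# an independent check on the coordinate-descent solver.
admm_glasso <- function(sigma, lam, rho = 1, n_iter = 2000, tol = 1e-10) {
  p <- nrow(sigma)
  Zm <- diag(p)
  U <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  Om <- diag(p)
  for (it in seq_len(n_iter)) {
    e <- eigen(rho * (Zm - U) - sigma, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Om <- e$vectors %*% (d * t(e$vectors))
    Z_old <- Zm
    Zm <- soft(Om + U, lam / rho)
    U <- U + Om - Zm
    if (max(abs(Zm - Z_old)) < tol && max(abs(Om - Zm)) < tol) break
  }
  (Zm + t(Zm)) / 2
}

# build a small column data set (upsilon/s12 per subject) from simulated
# Gaussian data, for evidence and z-update tests
make_column_data <- function(p, n_subjects, n, lambda = 0.1, seed = 1) {
  set.seed(seed)
  omega <- circle_precision(p)
  ups <- list()
  s12 <- list()
  for (s in seq_len(n_subjects)) {
    y <- sample_timeseries(omega, n)
    S <- tcrossprod(y)
    part <- partition_column(omega, S, p)
    o11inv <- chol2inv(chol(part$omega11))
    ups[[s]] <- compute_upsilon(part$s22, lambda, o11inv)
    s12[[s]] <- part$s12
  }
  list(ups = ups, s12 = s12)
}

# batch-means Monte-Carlo standard error of a chain mean
mcse <- function(x, n_batches = 20) hierprec:::mcse_batch(x, n_batches)
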