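`%inside%` <- function(x, r) x > r[1] & x < r[2]

test_that("Schur-complement draws follow their Gamma conditional", {
  set.seed(10)
  # n_s = 2, S22 + lambda = 2: Gamma(2, 1), mean 2
  x <- draw_nu(2, 1.5, 0.5, n = 1e5)
  expect_true(all(x > 0))
  expect_equal(mean(x), 2, tolerance = 0.02)
  ks <- suppressWarnings(ks.test(x, pgamma, shape = 2, rate = 1))
  expect_lt(unname(ks$statistic), 0.01)
  expect_error(draw_nu(2, -1, 0.5), "positive")
})

test_that("column regression precision scales the minor inverse", {
  o11inv <- chol2inv(chol(circle_precision(6)[1:5, 1:5]))
  expect_equal(compute_upsilon(1, 0, o11inv), o11inv)
  expect_equal(compute_upsilon(2, 2, o11inv), 2 * compute_upsilon(1, 1, o11inv))
  # circle(6), column 6, lambda = 0, S22 = 1: inverse of the leading block
  ups <- compute_upsilon(1, 0, o11inv)
  expect_equal(ups %*% circle_precision(6)[1:5, 1:5], diag(5),
               tolerance = 1e-12)
})

test_that("column strength draws honour the spike and match the conjugate
           posterior", {
  set.seed(11)
  ups <- diag(2) * 0.5
  # pure spike: exact zeros
  u0 <- draw_column_strengths(ups, c(1, 1), c(0, 0), c(1, 1), c(0, 0))
  expect_identical(u0, c(0, 0))
  # no-data limit: prior recovery N(mu, sigma^2)
  tiny <- diag(2) * 1e-12
  draws <- t(replicate(2e4, draw_column_strengths(
    tiny, c(0, 0), c(0.4, -0.2), c(0.5, 0.3), c(1, 1))))
  expect_equal(colMeans(draws), c(0.4, -0.2), tolerance = 0.02)
  expect_equal(apply(draws, 2, sd), c(0.5, 0.3), tolerance = 0.02)
  # p = 3 column with data: empirical moments match the analytic Gaussian
  set.seed(12)
  cd <- make_column_data(3, 1, 5, lambda = 0.3, seed = 5)
  mu12 <- c(0.2, -0.1)
  sig12 <- c(0.4, 0.6)
  Q <- cd$ups[[1]] + diag(1 / sig12^2)
  mean_an <- solve(Q, -cd$s12[[1]] + mu12 / sig12^2)
  cov_an <- solve(Q)
  draws <- t(replicate(1e5, draw_column_strengths(
    cd$ups[[1]], cd$s12[[1]], mu12, sig12, c(1, 1))))
  se <- sqrt(diag(cov_an) / 1e5)
  expect_true(all(abs(colMeans(draws) - mean_an) < 2.5 * se))
  expect_equal(cov(draws), cov_an, tolerance = 0.02)
})

test_that("group-mean draws follow the printed conjugate normal", {
  set.seed(13)
  # single subject, sigma = chi = 1, u = 2: posterior N(1, 1/2)
  u <- matrix(2, 1, 1)
  draws <- replicate(1e5, update_mu_column(u, 1, 1, 1))
  expect_equal(mean(draws), 1, tolerance = 0.01)
  expect_equal(var(draws), 0.5, tolerance = 0.01)
  # diffuse-chi limit: posterior mean tends to the sample mean of u
  u5 <- matrix(c(0.3, 0.5, 0.1, 0.2, 0.4), 5, 1)
  draws <- replicate(2e4, update_mu_column(u5, 0.3, 1e6, 1))
  expect_equal(mean(draws), mean(u5), tolerance = 0.005)
  # excluded edges refresh from N(0, chi^2)
  set.seed(14)
  draws <- replicate(2e4, update_mu_column(u, 1, 0.8, 0))
  expect_equal(mean(draws), 0, tolerance = 0.02)
  expect_equal(sd(draws), 0.8, tolerance = 0.01)
  # 1-D quadrature check of the posterior mean
  uq <- matrix(c(1.2, 0.7, 1.5), 3, 1)
  sig <- 0.5
  chi <- 1.3
  post <- function(m) {
    exp(dnorm(m, 0, chi, log = TRUE) +
          colSums(sapply(m, function(mm) dnorm(uq, mm, sig, log = TRUE))))
  }
  z0 <- integrate(post, -10, 10)$value
  mean_quad <- integrate(function(m) m * post(m), -10, 10)$value / z0
  draws <- replicate(1e5, update_mu_column(uq, sig, chi, 1))
  expect_equal(mean(draws), mean_quad, tolerance = 3 * sd(draws) / sqrt(1e5))
})

test_that("log-sigma random walk targets the right posterior", {
  set.seed(15)
  h <- default_hyperconstants()
  # no included edges: draws come from the log-normal prior
  draws <- replicate(2e4, update_sigma(matrix(0, 1, 1), 0, 0, 1)$sigma12)
  expect_equal(mean(log(draws)), log(0.5), tolerance = 0.02)
  expect_equal(sd(log(draws)), 1, tolerance = 0.02)
  # 50 subjects with u ~ N(0, 0.2^2): posterior concentrates near 0.2
  set.seed(16)
  u <- matrix(rnorm(50, 0, 0.2), 50, 1)
  post <- function(s) {
    exp(dnorm(log(s), log(h$m_sigma), h$s_sigma, log = TRUE) - log(s) +
          colSums(sapply(s, function(ss) dnorm(u, 0, ss, log = TRUE))))
  }
  z0 <- integrate(post, 1e-4, 5)$value
  mean_quad <- integrate(function(s) s * post(s), 1e-4, 5)$value / z0
  expect_lt(abs(mean_quad - 0.2), 0.05)
  sig <- 0.5
  acc <- 0
  chain <- numeric(4000)
  for (i in seq_along(chain)) {
    st <- update_sigma(u, 0, 1, sig, h, step = 0.3)
    sig <- st$sigma12
    acc <- acc + st$accepted
    chain[i] <- sig
  }
  expect_equal(mean(chain[-(1:500)]), mean_quad, tolerance = 0.02)
  rate <- acc / length(chain)
  expect_gt(rate, 0.1)
  expect_lt(rate, 0.9)
})

test_that("global-scale update is positive and tracks the mean magnitudes", {
  set.seed(17)
  st <- list(chi = 1, xi = 1)
  # likelihood dominance: many large means pin chi near their RMS
  mu_big <- rnorm(400, 0, 3)
  draws <- replicate(2000, {
    st <<- update_chi(mu_big, st$xi, 0.7)
    st$chi
  })
  expect_true(all(draws > 0))
  expect_equal(mean(draws), sqrt(mean(mu_big^2)), tolerance = 0.1)
})

test_that("sparsity-level update follows Beta-Bernoulli conjugacy", {
  set.seed(18)
  Zempty <- matrix(0L, 4, 4)
  d <- replicate(1e5, update_a(Zempty))
  expect_equal(mean(d), 6 / 18, tolerance = 0.005)  # Beta(6, 12)
  expect_equal(var(d), 6 * 12 / (18^2 * 19), tolerance = 0.001)
  Zfull <- matrix(1L, 4, 4)
  d <- replicate(1e4, update_a(Zfull))
  expect_equal(mean(d), 12 / 18, tolerance = 0.005)  # Beta(12, 6)
  # prior alone puts most mass in (0.3, 0.7)
  expect_gt(mean(rbeta(1e5, 6, 6) %inside% c(0.3, 0.7)), 0.8)
})

test_that("diagonal-rate update matches its quadrature posterior", {
  set.seed(19)
  # p = 2, unit diagonal: Gamma(7/3, 1)
  d <- replicate(1e5, update_lambda(c(1, 1)))
  expect_true(all(d > 0))
  post <- function(l) l^(1 / 3 - 1) * (l / 2)^2 * exp(-l)
  z0 <- integrate(post, 0, 60)$value
  mean_quad <- integrate(function(l) l * post(l), 0, 60)$value / z0
  expect_equal(mean_quad, 7 / 3, tolerance = 1e-6)
  expect_equal(mean(d), mean_quad, tolerance = 0.02)
  # doubling the diagonal halves the posterior mean
  d2 <- replicate(1e5, update_lambda(c(2, 2)))
  expect_equal(mean(d2), mean(d) / 2, tolerance = 0.02)
  expect_error(update_lambda(c(1, -1)), "positive")
})
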