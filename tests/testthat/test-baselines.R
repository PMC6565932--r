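test_that("naive inversion reproduces exact small cases", {
  # two-node covariance [[1, r], [r, 1]]: partial correlation r
  r <- 0.6
  ch <- chol(matrix(c(1, r, r, 1), 2))
  set.seed(40)
  y <- t(ch) %*% matrix(rnorm(2 * 2000), 2)
  y <- y - rowMeans(y)
  panel <- ts_panel(list(y))
  est <- naive_partial_correlation(panel)
  # inverse of the estimate reproduces the sample covariance
  expect_equal(chol2inv(chol(est$omega[[1]])), tcrossprod(y) / 2000,
               tolerance = 1e-10)
  expect_equal(est$pcorr[[1]][1, 2], cor(y[1, ], y[2, ]), tolerance = 1e-6)
  # consistency under independence
  set.seed(41)
  big <- ts_panel(list(matrix(rnorm(4 * 1e5), 4)))
  pc <- naive_partial_correlation(big)$pcorr[[1]]
  expect_lt(max(abs(pc[upper.tri(pc)])), 0.02)
  # singular covariance flagged
  expect_error(naive_partial_correlation(ts_panel(list(matrix(rnorm(8), 4)))),
               "singular")
})

test_that("Tikhonov estimate augments the diagonal before inversion", {
  sig <- circle_precision(4)  # any PD matrix works as a covariance here
  expect_equal(tikhonov(sig, 0), chol2inv(chol(sig)))
  expect_equal(tikhonov(diag(3), 1), diag(3) / 2)
  expect_lt(max(abs(tikhonov(diag(3), 1e8))), 1e-7)
  expect_error(tikhonov(sig, -1))
})

test_that("ridge selection minimises the group-coherence objective", {
  set.seed(42)
  ds <- generate_dataset(sim_spec("circle", 6, 5, 40))
  grid <- 10^seq(-4, 0, length.out = 12)
  sel <- select_tikhonov_lambda(ds$panel, grid)
  expect_true(sel$lambda %in% grid)
  expect_equal(sel$objective$objective[match(sel$lambda, grid)],
               min(sel$objective$objective))
  # deterministic
  sel2 <- select_tikhonov_lambda(ds$panel, grid)
  expect_identical(sel$objective, sel2$objective)
  # single subject with plentiful data wants the lightest touch
  set.seed(43)
  one <- ts_panel(list(sample_timeseries(circle_precision(4), 2e4)))
  expect_equal(select_tikhonov_lambda(one, grid)$lambda, min(grid))
  expect_error(select_tikhonov_lambda(ds$panel, numeric(0)), "non-empty")
})

test_that("graphical lasso solves its penalised likelihood", {
  set.seed(44)
  A <- matrix(rnorm(25), 5)
  sig <- crossprod(A) / 5 + diag(5) * 0.5
  # unpenalised: plain inverse
  expect_equal(glasso(sig, 0)$omega, chol2inv(chol(sig)), tolerance = 1e-8)
  # heavy penalty: diagonal solution
  heavy <- glasso(sig, 100)$omega
  off <- heavy
  diag(off) <- 0
  expect_equal(off, matrix(0, 5, 5))
  # objective within 1e-6 of an independent convex solver (ADMM route)
  for (lam in c(0.05, 0.2)) {
    fit <- glasso(sig, lam)
    oracle <- admm_glasso(sig, lam)
    obj_fit <- hierprec:::glasso_objective(fit$omega, sig, lam)
    obj_orc <- hierprec:::glasso_objective(oracle, sig, lam)
    expect_gt(obj_fit, obj_orc - 1e-6)
    expect_lt(abs(obj_fit - obj_orc), 1e-4)
    expect_true(is_positive_definite(fit$omega))
  }
  # sparsity is monotone in the penalty
  nnz <- sapply(c(0.01, 0.1, 0.3, 1), function(l) {
    om <- glasso(sig, l)$omega
    sum(abs(om[upper.tri(om)]) > 1e-8)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("Wishart posterior mean follows the printed closed form", {
  expect_equal(wishart_posterior_mean(matrix(0, 3, 3), 0), diag(3))
  expect_equal(wishart_posterior_mean(diag(10, 2), 10), diag(2))
  # likelihood dominance: S = n Sigma recovers the precision
  sig <- matrix(c(1, 0.4, 0.4, 1), 2)
  n <- 1e6
  est <- wishart_posterior_mean(n * sig, n)
  expect_equal(est, solve(sig), tolerance = 1e-3)
})

test_that("hierarchical Wishart conditionals match their printed forms", {
  set.seed(45)
  omega <- circle_precision(3)
  y <- sample_timeseries(omega, 50)
  panel <- standardise_panel(ts_panel(list(y)))
  ips <- inner_products(panel)
  nu0 <- 6
  # subject conditional with frozen B = I (iid Wishart draws)
  fit <- hier_wishart_gibbs(ips, nu0, n_iter = 4000, n_warmup = 0,
                            fix_B = diag(3))
  target <- (nu0 + 50) * chol2inv(chol(diag(3) + ips$S[[1]]))
  expect_equal(fit$omega_mean[[1]], target, tolerance = 0.05)
  # group conditional with frozen subject precisions
  omg <- list(circle_precision(3), diag(3))
  ips2 <- inner_products(standardise_panel(ts_panel(list(y, y))))
  fitB <- hier_wishart_gibbs(ips2, nu0, n_iter = 4000, n_warmup = 0,
                             fix_omega = omg)
  scale_B <- chol2inv(chol(diag(3) + Reduce(`+`, omg)))
  expect_equal(fitB$B_mean, (2 * nu0 + 3) * scale_B, tolerance = 0.05)
  # full Gibbs keeps draws PD
  full <- hier_wishart_gibbs(ips2, nu0, n_iter = 50, n_warmup = 20)
  for (om in full$omega_mean) expect_true(is_positive_definite(om))
})

test_that("degrees-of-freedom selection is reproducible and coherent", {
  set.seed(46)
  group <- circle_precision(4)
  omegas <- perturb_subjects(group, 8, 0.02)
  panel <- ts_panel(Map(sample_timeseries, omegas, rep(150, 8)))
  cand <- c(5, 40, 200)
  set.seed(1)
  s1 <- select_nu0(panel, cand, n_iter = 150, n_warmup = 100)
  set.seed(1)
  s2 <- select_nu0(panel, cand, n_iter = 150, n_warmup = 100)
  expect_identical(s1$objective, s2$objective)
  expect_equal(s1$objective$objective[match(s1$nu0, cand)],
               min(s1$objective$objective))
  # strong between-subject agreement prefers heavier pooling than nu0 = p+1
  expect_gt(s1$nu0, 5)
  expect_error(select_nu0(ts_panel(panel$subjects[1:3]), cand), "4 subjects")
})
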