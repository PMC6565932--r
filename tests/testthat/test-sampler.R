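test_that("sampler runs are reproducible from the seed", {
  set.seed(30)
  ds <- generate_dataset(sim_spec("circle", 2, 4, 30))
  cfg <- sampler_config("strong", n_samples = 200, n_warmup = 100, thin = 5,
                        seed = 99, store_draws = TRUE)
  f1 <- run_sampler(ds$panel, cfg)
  f2 <- run_sampler(ds$panel, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$group_pcorr, f2$group_pcorr)
  cfg$seed <- 100L
  f3 <- run_sampler(ds$panel, cfg)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every stored precision draw is positive definite", {
  set.seed(31)
  ds <- generate_dataset(sim_spec("circle", 3, 5, 40))
  for (model in c("strong", "weak", "single_subject", "bayesian_glasso",
                  "ssvs")) {
    cfg <- sampler_config(model, n_samples = 150, n_warmup = 50, thin = 5,
                          seed = 7, store_draws = TRUE)
    fit <- run_sampler(ds$panel, cfg)
    expect_equal(fit$pd_failures, 0)
    dims <- dim(fit$draws)
    for (k in seq_len(dims[4])) {
      for (s in seq_len(dims[3])) {
        expect_true(is_positive_definite(fit$draws[, , s, k]))
      }
    }
  }
})

test_that("weak model converges to the likelihood solution with much data", {
  set.seed(32)
  omega <- circle_precision(3)
  panel <- ts_panel(list(sample_timeseries(omega, 5000)))
  fit <- run_sampler(panel, sampler_config("weak", n_samples = 800,
                                           n_warmup = 200, thin = 4,
                                           seed = 5))
  target <- chol2inv(chol(tcrossprod(standardise_panel(panel)$subjects[[1]]) /
                            5000))
  rel <- norm(fit$omega_mean[[1]] - target, "F") / norm(target, "F")
  expect_lt(rel, 0.05)
})

test_that("compiled sweep and R reference sweep agree on a toy posterior", {
  set.seed(33)
  ds <- generate_dataset(sim_spec("circle", 2, 3, 60))
  panel <- standardise_panel(ds$panel)
  # compiled path
  fit <- run_sampler(panel, sampler_config("weak", n_samples = 3000,
                                           n_warmup = 500, thin = 3,
                                           seed = 11, store_draws = TRUE))
  # R reference path
  set.seed(11)
  st <- initial_state(panel, full_graph = TRUE)
  for (i in 1:500) st <- gibbs_sweep(st, "weak")
  acc <- matrix(0, 3, 3)
  n_keep <- 1500
  keep_pc <- array(0, c(3, 3, n_keep))
  for (i in seq_len(n_keep)) {
    st <- gibbs_sweep(st, "weak")
    st <- gibbs_sweep(st, "weak")
    pc <- (partial_correlation(st$Omega[[1]]) +
             partial_correlation(st$Omega[[2]])) / 2
    keep_pc[, , i] <- pc
    acc <- acc + pc
  }
  ref <- acc / n_keep
  # Monte-Carlo uncertainty of the R reference chain (batch means)
  for (e in list(c(1, 2), c(1, 3), c(2, 3))) {
    se_r <- mcse(keep_pc[e[1], e[2], ])
    cpp_draws <- apply(fit$draws, 4, function(om) {
      (partial_correlation(om[, , 1]) + partial_correlation(om[, , 2]))[
        e[1], e[2]] / 2
    })
    se_c <- mcse(cpp_draws)
    expect_lt(abs(fit$group_pcorr[e[1], e[2]] - ref[e[1], e[2]]),
              4 * sqrt(se_r^2 + se_c^2) + 0.005)
  }
})

test_that("one reference sweep preserves positive definiteness", {
  set.seed(34)
  ds <- generate_dataset(sim_spec("circle", 2, 3, 25))
  st <- initial_state(standardise_panel(ds$panel))
  for (i in 1:5) {
    st <- gibbs_sweep(st, "strong")
    for (om in st$Omega) expect_true(is_positive_definite(om))
  }
})

test_that("sigma acceptance lands in a healthy band after adaptation", {
  set.seed(35)
  ds <- generate_dataset(sim_spec("circle", 4, 5, 60))
  fit <- run_sampler(ds$panel, sampler_config("weak", n_samples = 400,
                                              n_warmup = 400, thin = 4,
                                              seed = 2))
  expect_gt(fit$sigma_accept, 0.1)
  expect_lt(fit$sigma_accept, 0.9)
})

test_that("short-data runs warn instead of failing", {
  set.seed(36)
  panel <- ts_panel(list(matrix(rnorm(5 * 3), 5)))
  expect_warning(
    run_sampler(panel, sampler_config("weak", n_samples = 50, n_warmup = 20,
                                      thin = 5, seed = 1)),
    "more nodes"
  )
  expect_error(
    run_sampler(ts_panel(list(matrix(c(1, NA, 2, 3, 4, 5), 2))),
                sampler_config("weak")),
    "non-finite"
  )
})
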