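test_that("RMS error behaves like a metric over unordered pairs", {
  pc <- partial_correlation(circle_precision(4))
  expect_equal(rms_error(pc, circle_precision(4)), 0)
  # single discrepant entry of 0.3 on p = 3: sqrt(0.09 / 3)
  est <- diag(3)
  est[1, 2] <- est[2, 1] <- 0.3
  truth <- diag(3)
  expect_equal(rms_error(est, truth), sqrt(0.09 / 3))
  # invariant under a joint node relabelling
  set.seed(70)
  om <- circle_precision(5)
  est <- partial_correlation(om) + matrix(rnorm(25, sd = 0.01), 5)
  est <- (est + t(est)) / 2
  perm <- sample(5)
  expect_equal(rms_error(est, om),
               rms_error(est[perm, perm], om[perm, perm]))
  expect_error(rms_error(diag(3), diag(4)), "dimension")
  # precision-space comparison skips the normalisation
  expect_equal(rms_error(om, om, space = "precision"), 0)
})

test_that("normalised RMS anchors the naive estimator at one", {
  e <- c(0.2, 0.1)
  expect_equal(normalise_rms(e, e), c(1, 1))
  expect_equal(normalise_rms(c(0.1), c(0.2)), 0.5)
  expect_true(all(normalise_rms(runif(5), runif(5) + 0.1) >= 0))
  expect_error(normalise_rms(e, c(0.2, 0)), "zero")
  expect_error(normalise_rms(e, c(0.1)), "same subjects")
})

test_that("edge AUC equals the rank statistic and its known endpoints", {
  g <- (circle_precision(6) != 0) * 1L
  diag(g) <- 0L
  # scores equal to truth: perfect separation
  expect_equal(edge_roc_auc(g * 1.0, g), 1)
  # random scores: near chance on a larger problem
  set.seed(71)
  g30 <- matrix(0L, 30, 30)
  g30[upper.tri(g30)] <- rbinom(435, 1, 0.3)
  g30 <- g30 + t(g30)
  aucs <- replicate(200, {
    sc <- matrix(0, 30, 30)
    sc[upper.tri(sc)] <- runif(435)
    edge_roc_auc(sc + t(sc), g30)
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
  # agrees with brute-force pairwise comparison (midranks for ties)
  set.seed(72)
  for (rep in 1:20) {
    n <- 40
    lab <- rbinom(n, 1, 0.4)
    if (all(lab == 0) || all(lab == 1)) next
    sc <- round(runif(n), 1)  # force ties
    brute <- {
      pos <- sc[lab == 1]
      neg <- sc[lab == 0]
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      mean(cmp)
    }
    expect_equal(edge_roc_auc(sc, lab), brute, tolerance = 1e-12)
  }
  # invariant under strictly monotone transforms
  sc <- matrix(0, 6, 6)
  sc[upper.tri(sc)] <- runif(15)
  sc <- sc + t(sc)
  expect_equal(edge_roc_auc(sc, g), edge_roc_auc(exp(3 * sc), g))
  expect_error(edge_roc_auc(sc, g * 0L), "undefined")
})

test_that("posterior summaries expose edge tables and credible intervals", {
  set.seed(73)
  ds <- generate_dataset(sim_spec("circle", 2, 4, 80))
  fit <- run_sampler(ds$panel, sampler_config("strong", n_samples = 400,
                                              n_warmup = 200, thin = 4,
                                              seed = 3, store_draws = TRUE))
  sm <- summarise_posterior(fit)
  expect_equal(nrow(sm$group), 6)
  expect_true(all(sm$group$edge_prob >= 0 & sm$group$edge_prob <= 1))
  # intervals bracket the posterior mean for these unimodal marginals
  expect_true(all(sm$group$lower <= sm$group$pcorr_mean + 1e-8))
  expect_true(all(sm$group$upper >= sm$group$pcorr_mean - 1e-8))
  expect_equal(nrow(sm$subjects), 2 * 6)
  # degenerate one-draw archive: summary equals that draw
  cfg1 <- sampler_config("weak", n_samples = 1, n_warmup = 30, thin = 1,
                         seed = 5, store_draws = TRUE)
  f1 <- run_sampler(ds$panel, cfg1)
  expect_equal(f1$pcorr[[1]], partial_correlation(f1$draws[, , 1, 1]))
})

test_that("tidy and glance produce the broom-style views", {
  set.seed(74)
  ds <- generate_dataset(sim_spec("circle", 3, 4, 60))
  fit <- run_sampler(ds$panel, sampler_config("strong", n_samples = 200,
                                              n_warmup = 100, thin = 4,
                                              seed = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_true(all(c("i", "j", "estimate", "edge_prob") %in% names(td)))
  tds <- tidy(fit, subjects = TRUE)
  expect_equal(nrow(tds), 18)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$model, "strong")
  expect_equal(gl$pd_failures, 0)
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
  sc <- score_estimates(fit$pcorr, ds$truth,
                        naive_partial_correlation(ds$panel)$pcorr, "strong")
  expect_s3_class(plot_rms_comparison(sc), "ggplot")
})
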