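test_that("circle precision has the benchmark entries and sparsity", {
  om <- circle_precision(6)
  expect_equal(om[1, 2], 0.5)
  expect_equal(om[1, 6], 0.4)
  expect_equal(om[1, 3], 0)
  expect_equal(diag(om), rep(1, 6))
  expect_equal(om, t(om))
  # 6 of 15 unordered pairs carry an edge: sparsity 0.60
  nz <- sum(om[upper.tri(om)] != 0)
  expect_equal(nz, 6)
  expect_equal(1 - nz / 15, 0.60)
  for (p in c(3, 10, 50, 100)) {
    expect_true(is_positive_definite(circle_precision(p)))
  }
  expect_error(circle_precision(2), "p >= 3")
})

test_that("subject perturbation preserves structure and spread", {
  group <- circle_precision(5)
  # sd = 0 with fixed signs: all subjects equal the rescaled group matrix
  set.seed(50)
  subs <- perturb_subjects(group, 3, 0, random_signs = FALSE)
  target <- hierprec:::rescale_unit_variance(group)
  for (om in subs) expect_equal(om, target, tolerance = 1e-10)
  # with the group signs kept, the repair rarely triggers and the zero
  # pattern survives (rescaling preserves structural zeros)
  set.seed(51)
  subs <- perturb_subjects(group, 20, 0.02, random_signs = FALSE)
  mask <- group == 0 & upper.tri(group)
  for (om in subs) {
    expect_lt(max(abs(om[mask])), 0.02)
    expect_true(is_positive_definite(om))
  }
  # per-edge spread over many subjects is of the order of the requested sd;
  # the exact value is modulated by the unit-variance rescaling, which mixes
  # the perturbations of neighbouring edges through the matrix inversions
  set.seed(52)
  subs <- perturb_subjects(group, 500, 0.02, random_signs = FALSE)
  vals <- sapply(subs, function(om) om[1, 2])
  scale_12 <- abs(target[1, 2] / group[1, 2])
  expect_gt(sd(vals), 0.5 * 0.02 * scale_12)
  expect_lt(sd(vals), 4 * 0.02 * scale_12)
  expect_equal(mean(vals), target[1, 2], tolerance = 0.01)
  # the random-sign path still yields PD subject matrices
  set.seed(53)
  for (om in perturb_subjects(group, 5, 0.15)) {
    expect_true(is_positive_definite(om))
    expect_equal(om, t(om))
  }
})

test_that("time-series generator draws from the intended Gaussian", {
  set.seed(53)
  y <- sample_timeseries(diag(3), 1e5)
  expect_lt(max(abs(tcrossprod(y) / 1e5 - diag(3))), 0.02)
  set.seed(9)
  y1 <- sample_timeseries(circle_precision(4), 10)
  set.seed(9)
  y2 <- sample_timeseries(circle_precision(4), 10)
  expect_identical(y1, y2)
  # consistency: naive partial correlation recovers the circle edge
  set.seed(54)
  y <- sample_timeseries(circle_precision(6), 1e5)
  pc <- naive_partial_correlation(ts_panel(list(y)))$pcorr[[1]]
  expect_equal(pc[1, 2], -0.5, tolerance = 0.01)
})

test_that("random-edge design follows its generative recipe", {
  set.seed(55)
  ds <- generate_dataset(sim_spec("random_edges", 4, 6, 50))
  # truth = probability * strengths; absent edges exactly zero
  absent <- ds$truth$graph == 0 & upper.tri(ds$truth$graph)
  for (om in ds$truth$omega) {
    expect_true(all(om[absent] == 0))
  }
  expect_equal(dim(ds$panel$subjects[[1]]), c(6, 50))
  # stochastic edges are toggled at the Bernoulli rate
  set.seed(56)
  p6 <- matrix(0.5, 3, 3)
  hits <- replicate(1e4, hierprec:::realised_edge_mask(p6)[1, 2])
  expect_equal(mean(hits), 0.5, tolerance = 0.02)
  # degenerate probabilities: all-on reduces to fixed-precision sampling
  all_on <- matrix(1, 3, 3)
  expect_equal(hierprec:::realised_edge_mask(all_on),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  all_off <- matrix(0, 3, 3)
  expect_equal(hierprec:::realised_edge_mask(all_off), matrix(0, 3, 3))
})

test_that("conditional G-Wishart draws respect the graph and the density", {
  # complete graph: ordinary Wishart with df + p - 1 degrees of freedom
  set.seed(57)
  p <- 3
  full <- matrix(1, p, p) - diag(p)
  draws <- gwishart_draw(full, df = 4, n = 4000, burnin = 100, thin = 2)
  mn <- Reduce(`+`, draws) / length(draws)
  expect_equal(mn, (4 + p - 1) * diag(p), tolerance = 0.25)
  # empty graph: independent diagonal draws, off-diagonals exactly zero
  set.seed(58)
  empty <- matrix(0, 3, 3)
  draws <- gwishart_draw(empty, df = 5, scale = diag(2, 3), n = 2000,
                         burnin = 20)
  for (d in draws) expect_equal(d[upper.tri(d)], rep(0, 3))
  diags <- sapply(draws, function(d) d[1, 1])
  # Gamma(df/2, C11/2) with C = scale^{-1}: mean df / C11 = 10
  expect_equal(mean(diags), 10, tolerance = 0.3)
  # circle graph: off-graph entries are structural zeros, draws PD
  set.seed(59)
  g5 <- (circle_precision(5) != 0) * 1L
  diag(g5) <- 0L
  draws <- gwishart_draw(g5, df = 4, n = 50, burnin = 50)
  offg <- g5 == 0 & upper.tri(g5)
  for (d in draws) {
    expect_equal(d[offg], rep(0, sum(offg)))
    expect_true(is_positive_definite(d))
  }
})

test_that("structured group designs share the graph and scale with df", {
  set.seed(60)
  g <- (circle_precision(6) != 0) * 1L
  diag(g) <- 0L
  spec <- sim_spec("gwishart_structured", 12, 6, 30, df_subject = 50,
                   graph = g)
  ds <- generate_dataset(spec)
  offg <- g == 0 & upper.tri(g)
  for (om in ds$truth$omega) {
    expect_equal(om[offg], rep(0, sum(offg)))
    expect_true(is_positive_definite(om))
  }
  # lower subject df means more between-subject spread
  cv_edge <- function(df_subject) {
    set.seed(61)
    spec <- sim_spec("gwishart_structured", 30, 6, 5, df_subject = df_subject,
                     graph = g)
    ds <- generate_dataset(spec)
    vals <- sapply(ds$truth$pcorr, function(m) m[1, 2])
    sd(vals) / abs(mean(vals))
  }
  expect_gt(cv_edge(50), cv_edge(400))
  expect_error(generate_dataset(sim_spec("gwishart_structured", 2, 6, 10,
                                         graph = g)), "df_subject")
})

test_that("presets reproduce the benchmark dimensions", {
  s1 <- sim_preset("sim1")
  expect_equal(s1$n_subjects, 5L)
  expect_equal(s1$p, 6L)
  expect_equal(s1$n, rep(18L, 5))
  expect_equal(sim_preset("sim2")$n_subjects, 25L)
  expect_equal(sim_preset("sim3")$n[1], 500L)
  expect_equal(sim_preset("sim4")$n[1], 1000L)
  s6 <- sim_preset("sim6")
  expect_equal(s6$p, 25L)
  expect_equal(s6$structure, "random_edges")
  expect_equal(sim_preset("sim7")$subject_sd, 0.05)
  s8 <- sim_preset("sim8")
  expect_equal(s8$p, 30L)
  expect_equal(s8$subject_sd, 0.15)
  expect_equal(s8$n[1], 1100L)  # documented default for the ambiguous row
  expect_equal(sim_preset("sim8", n = 200)$n[1], 200L)
  # ground truth of every circle preset is PD
  for (id in c("sim1", "sim2")) {
    set.seed(62)
    ds <- generate_dataset(id)
    for (om in ds$truth$omega) expect_true(is_positive_definite(om))
  }
})
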