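#' Circle-structured benchmark precision matrix
#'
#' The classic sparse benchmark: unit diagonal, 0.5 on the first
#' off-diagonal, 0.4 linking the first and last nodes, zero elsewhere.
#'
#' @param p Node count (>= 3).
#' @return p x p symmetric positive-definite precision matrix.
#' @export
circle_precision <- function(p) {
  if (p < 3) stop("circle model needs p >= 3", call. = FALSE)
  omega <- diag(p)
  for (i in seq_len(p - 1)) {
    omega[i, i + 1] <- omega[i + 1, i] <- 0.5
  }
  omega[1, p] <- omega[p, 1] <- 0.4
  omega
}

#' Draw zero-mean Gaussian time series with a given precision
#'
#' `n` independent draws from `N(0, omega^{-1})`, arranged nodes x time.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @param n Number of time points (>= 1).
#' @return p x n numeric matrix.
#' @export
sample_timeseries <- function(omega, n) {
  stopifnot(n >= 1)
  ch <- chol(omega)
  p <- nrow(omega)
  backsolve(ch, matrix(stats::rnorm(p * n), p, n))
}

# invert to covariance, rescale to a correlation matrix, invert back: the
# scale-free way to put simulated subjects on the unit-variance convention
rescale_unit_variance <- function(omega) {
  sigma <- chol2inv(chol(omega))
  solve(stats::cov2cor(sigma))
}

#' Per-subject perturbations of a group precision matrix
#'
#' Assigns a random sign to each nonzero off-diagonal group edge (one sign
#' per edge, shared by all subjects), draws every subject's strength on
#' that edge from `N(signed group value, sd^2)`, repairs each resulting
#' matrix to the positive-definite cone with [nearest_pd()], and rescales
#' it to unit variance (correlation-scale covariance).
#'
#' @param group_omega Group-level precision matrix.
#' @param n_subjects Number of subjects.
#' @param sd Between-subject standard deviation of edge strengths (>= 0).
#' @param random_signs Draw the shared edge signs (default `TRUE`; `FALSE`
#'   keeps the group signs, useful for exact-reproduction checks).
#' @param epsilon Minimum eigenvalue enforced by the repair step.
#' @return List of p x p positive-definite subject precisions.
#' @export
perturb_subjects <- function(group_omega, n_subjects, sd,
                             random_signs = TRUE, epsilon = 1e-4) {
  stopifnot(sd >= 0)
  p <- nrow(group_omega)
  up <- upper.tri(group_omega)
  edges <- which(up & group_omega != 0)
  signs <- if (random_signs) {
    sample(c(-1, 1), length(edges), replace = TRUE)
  } else {
    rep(1, length(edges))
  }
  signed <- group_omega
  signed[edges] <- signs * group_omega[edges]
  signed[lower.tri(signed)] <- t(signed)[lower.tri(signed)]
  lapply(seq_len(n_subjects), function(s) {
    omega <- signed
    omega[edges] <- stats::rnorm(length(edges), signed[edges], sd)
    omega[lower.tri(omega)] <- t(omega)[lower.tri(omega)]
    omega <- nearest_pd(omega, epsilon)
    rescale_unit_variance(omega)
  })
}

#' Draw from a G-Wishart distribution conditional on a graph
#'
#' Block-Gibbs sampling of a precision matrix with density proportional to
#' `|Omega|^((df - 2)/2) exp(-tr(scale^{-1} Omega)/2)` restricted to the
#' cone of positive-definite matrices whose off-graph entries are zero.
#' Each sweep redraws every column: the on-graph strengths from their
#' Gaussian conditional and the Schur complement from
#' `Gamma(df/2, C22/2)`, which keeps every state positive definite.  With a
#' complete graph the draws are Wishart with `df + p - 1` degrees of
#' freedom and the given scale.
#'
#' @param graph Symmetric binary adjacency matrix (diagonal ignored).
#' @param df Shape degrees of freedom (> 2 for a proper distribution on a
#'   complete graph; >= 2 suffices on sparse graphs).
#' @param scale Scale matrix (default identity).
#' @param n Number of draws to return.
#' @param burnin Warm-up sweeps before the first draw (default 300).
#' @param thin Sweeps between kept draws (default 1).
#' @param init Optional starting matrix on the cone.
#' @return A p x p matrix if `n = 1`, else a list of matrices.
#' @export
gwishart_draw <- function(graph, df, scale = diag(nrow(graph)), n = 1,
                          burnin = 300, thin = 1, init = NULL) {
  p <- nrow(graph)
  stopifnot(isSymmetric(unname(graph * 1)), df > 0)
  C <- chol2inv(chol(scale))
  omega <- if (is.null(init)) diag(p) else init
  draws <- vector("list", n)
  total <- burnin + n * thin
  kept <- 0L
  for (iter in seq_len(total)) {
    for (j in seq_len(p)) {
      keep <- setdiff(seq_len(p), j)
      inc <- which(graph[keep, j] != 0)
      o11inv <- chol2inv(chol(omega[keep, keep, drop = FALSE]))
      u <- numeric(p - 1)
      if (length(inc)) {
        Q <- C[j, j] * o11inv[inc, inc, drop = FALSE]
        ch <- chol(Q)
        mean_u <- backsolve(ch, forwardsolve(t(ch), -C[keep, j][inc]))
        u[inc] <- mean_u + backsolve(ch, stats::rnorm(length(inc)))
      }
      nu <- stats::rgamma(1, shape = df / 2, rate = C[j, j] / 2)
      omega[keep, j] <- u
      omega[j, keep] <- u
      omega[j, j] <- nu + drop(crossprod(u, o11inv %*% u))
    }
    if (iter > burnin && (iter - burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[[kept]] <- omega
    }
  }
  if (n == 1) draws[[1]] else draws
}

#' Simulation design specification
#'
#' @param structure One of `"circle"`, `"random_edges"`,
#'   `"gwishart_structured"`, `"custom_graph"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param p Node count (>= 3).
#' @param n Time points per subject (scalar or vector).
#' @param subject_sd Between-subject edge-strength standard deviation
#'   (circle designs).
#' @param edge_mean Mean edge strength of the random-edge design
#'   (default 0.25).
#' @param edge_sd Edge-strength standard deviation of the random-edge
#'   design (default 0.05).
#' @param df_group,df_subject G-Wishart degrees of freedom for the
#'   structured design.
#' @param graph Optional adjacency matrix (structured/custom designs).
#' @param sim_id Optional preset label.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(structure = c("circle", "random_edges",
                                   "gwishart_structured", "custom_graph"),
                     n_subjects, p, n, subject_sd = 0, edge_mean = 0.25,
                     edge_sd = 0.05, df_group = NULL, df_subject = NULL,
                     graph = NULL, sim_id = NULL) {
  structure_ <- match.arg(structure)
  stopifnot(p >= 3, n_subjects >= 1, subject_sd >= 0)
  n <- rep_len(n, n_subjects)
  structure(
    list(structure = structure_, n_subjects = as.integer(n_subjects),
         p = as.integer(p), n = as.integer(n), subject_sd = subject_sd,
         edge_mean = edge_mean, edge_sd = edge_sd, df_group = df_group,
         df_subject = df_subject, graph = graph, sim_id = sim_id),
    class = "sim_spec"
  )
}

#' Benchmark simulation presets
#'
#' Named presets reproducing the benchmark designs: `sim1` (5 subjects,
#' 6-node circle, 18 samples), `sim2`-`sim4` (25 subjects, 6-node circle,
#' 18/500/1000 samples), `sim6` (25 subjects, 25-node random-edge model,
#' 500 samples), `sim7` (25 subjects, 6-node circle, 25 samples, subject
#' sd 0.05) and `sim8` (25 subjects, 30-node circle, subject sd 0.15;
#' its sample count is ambiguous in published descriptions, so `n`
#' defaults to 1100 and can be overridden).
#'
#' @param id Preset name.
#' @param n Optional override of the per-subject sample count.
#' @return A [sim_spec()].
#' @export
sim_preset <- function(id = c("sim1", "sim2", "sim3", "sim4", "sim6",
                              "sim7", "sim8"), n = NULL) {
  id <- match.arg(id)
  spec <- switch(id,
    sim1 = sim_spec("circle", 5, 6, 18),
    sim2 = sim_spec("circle", 25, 6, 18),
    sim3 = sim_spec("circle", 25, 6, 500),
    sim4 = sim_spec("circle", 25, 6, 1000),
    sim6 = sim_spec("random_edges", 25, 25, 500),
    sim7 = sim_spec("circle", 25, 6, 25, subject_sd = 0.05),
    sim8 = sim_spec("circle", 25, 30, 1100, subject_sd = 0.15)
  )
  spec$sim_id <- id
  if (!is.null(n)) spec$n <- rep_len(as.integer(n), spec$n_subjects)
  spec
}

ground_truth <- function(omega_list, graph, group) {
  structure(
    list(
      omega = omega_list,
      pcorr = lapply(omega_list, pcorr_scale),
      graph = graph,
      group = group
    ),
    class = "ground_truth"
  )
}

# normalise a strength/precision matrix to the partial-correlation scale
# without inversion; works for indefinite "truth" matrices too
pcorr_scale <- function(m) {
  d <- sqrt(abs(diag(m)))
  p <- -m / tcrossprod(d)
  diag(p) <- 1
  p
}

#' Generate a synthetic multi-subject dataset
#'
#' Dispatches on the design structure and returns the data panel together
#' with the ground truth used for scoring.
#'
#' Circle designs with `subject_sd = 0` give every subject the same circle
#' precision; positive `subject_sd` perturbs subjects about the (randomly
#' signed) group matrix via [perturb_subjects()].  The random-edge design
#' draws per-edge inclusion probabilities uniformly from {0, 0.5, 1},
#' subject strengths from `N(edge_mean, edge_sd^2)` and toggles
#' 0.5-probability edges independently at every time point (each realised
#' matrix is repaired to the PD cone before the sample is drawn); its
#' ground truth is the elementwise product of the probability matrix and
#' the subject strengths.  The structured design draws a group matrix from
#' a conditional G-Wishart on the supplied graph (`df_group`, identity
#' scale, default `p - 1`) and subject matrices from a conditional
#' G-Wishart with the group matrix as scale (`df_subject`).
#'
#' @param spec A [sim_spec()] or preset name accepted by [sim_preset()].
#' @return List with `panel` (a [ts_panel()]) and `truth` (a
#'   `ground_truth` object: subject precisions, partial correlations,
#'   binary graph, group matrix).
#' @export
generate_dataset <- function(spec) {
  if (is.character(spec)) spec <- sim_preset(spec)
  stopifnot(inherits(spec, "sim_spec"))
  switch(spec$structure,
    circle = generate_circle(spec),
    random_edges = generate_random_edges(spec),
    gwishart_structured = generate_structured(spec),
    custom_graph = generate_structured(spec),
    stop("unknown structure: ", spec$structure, call. = FALSE)
  )
}

generate_circle <- function(spec) {
  group <- circle_precision(spec$p)
  omega_list <- if (spec$subject_sd > 0) {
    perturb_subjects(group, spec$n_subjects, spec$subject_sd)
  } else {
    replicate(spec$n_subjects, group, simplify = FALSE)
  }
  graph <- (group != 0) * 1L
  diag(graph) <- 0L
  panel <- ts_panel(Map(sample_timeseries, omega_list, spec$n))
  list(panel = panel, truth = ground_truth(omega_list, graph, group))
}

# one realised adjacency for the random-edge design: certain edges stay on,
# stochastic edges are toggled independently at their inclusion probability
realised_edge_mask <- function(prob) {
  mask <- (prob == 1) * 1
  up <- which(upper.tri(prob) & prob > 0 & prob < 1)
  on <- up[stats::runif(length(up)) < prob[up]]
  mask[on] <- 1
  mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
  diag(mask) <- 0
  mask
}

generate_random_edges <- function(spec) {
  p <- spec$p
  up <- upper.tri(matrix(0, p, p))
  prob <- matrix(0, p, p)
  prob[up] <- sample(c(0, 0.5, 1), sum(up), replace = TRUE)
  prob[lower.tri(prob)] <- t(prob)[lower.tri(prob)]
  omega_list <- vector("list", spec$n_subjects)
  panels <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    strength <- matrix(0, p, p)
    strength[up] <- stats::rnorm(sum(up), spec$edge_mean, spec$edge_sd)
    strength[lower.tri(strength)] <- t(strength)[lower.tri(strength)]
    truth <- prob * strength
    diag(truth) <- 1
    omega_list[[s]] <- truth
    y <- matrix(0, p, spec$n[s])
    for (t in seq_len(spec$n[s])) {
      omega_t <- strength * realised_edge_mask(prob)
      diag(omega_t) <- 1
      if (!is_positive_definite(omega_t)) {
        omega_t <- nearest_pd(omega_t, 0.01)
      }
      y[, t] <- sample_timeseries(omega_t, 1)
    }
    panels[[s]] <- y
  }
  graph <- (prob > 0) * 1L
  diag(graph) <- 0L
  group <- prob * spec$edge_mean
  diag(group) <- 1
  list(panel = ts_panel(panels),
       truth = ground_truth(omega_list, graph, group))
}

generate_structured <- function(spec) {
  if (is.null(spec$graph)) {
    stop("structured designs need an adjacency matrix in `spec$graph`",
         call. = FALSE)
  }
  graph <- (spec$graph != 0) * 1L
  graph <- pmax(graph, t(graph))
  diag(graph) <- 0L
  p <- nrow(graph)
  df_group <- if (is.null(spec$df_group)) p - 1 else spec$df_group
  df_subject <- spec$df_subject
  if (is.null(df_subject)) {
    stop("structured designs need `df_subject`", call. = FALSE)
  }
  group <- gwishart_draw(graph, df_group, diag(p))
  omega_list <- gwishart_draw(graph, df_subject, group, n = spec$n_subjects,
                              thin = 5)
  panel <- ts_panel(Map(sample_timeseries, omega_list, spec$n))
  list(panel = panel, truth = ground_truth(omega_list, graph, group))
}
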