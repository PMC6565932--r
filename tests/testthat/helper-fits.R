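# Shared fit cache: the benchmark-reproduction tests reuse the same MCMC
# runs, so each (dataset, model) pair is fitted once per test session.

.fit_cache <- new.env(parent = emptyenv())

# fixed study conditions for the benchmark reproduction: 5000 total sweeps
# (1000 warm-up), thinned to 400 kept draws
bench_config <- function(model, seed, store_draws = FALSE) {
  sampler_config(model, n_samples = 4000, n_warmup = 1000, thin = 10,
                 seed = seed, store_draws = store_draws)
}

bench_dataset <- function(id) {
  key <- paste0("data_", id)
  if (is.null(.fit_cache[[key]])) {
    set.seed(2024 + match(id, c("sim1", "sim2", "sim3", "sim4", "sim6",
                                "sim7", "sim8")))
    ds <- generate_dataset(sim_preset(id))
    ds$naive <- naive_partial_correlation(ds$panel)$pcorr
    .fit_cache[[key]] <- ds
  }
  .fit_cache[[key]]
}

bench_fit <- function(id, model) {
  key <- paste0(id, "_", model)
  if (is.null(.fit_cache[[key]])) {
    ds <- bench_dataset(id)
    seed <- 100 + nchar(id) + match(model, c("strong", "weak"))
    store <- id == "sim1"  # small archive kept for the PD audit
    .fit_cache[[key]] <- run_sampler(ds$panel,
                                     bench_config(model, seed, store))
  }
  .fit_cache[[key]]
}

bench_scores <- function(id, model) {
  ds <- bench_dataset(id)
  fit <- bench_fit(id, model)
  score_estimates(fit$pcorr, ds$truth, ds$naive, paste(id, model))
}
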