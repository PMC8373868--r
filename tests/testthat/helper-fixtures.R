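# Small deterministic helpers shared across test files.

# Quick parameter set for engine tests: short warmup/horizon, small tumor.
quick_params <- function(...) {
  model_params(warmup_cycles = 50L, max_cycles = 100L, N_0 = 20L, ...)
}

# Random small right-censored dataset for survival cross-checks.
random_surv <- function(n) {
  surv_data(sample(1:10, n, replace = TRUE),
            stats::runif(n) < 0.7)
}
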