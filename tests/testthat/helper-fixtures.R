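# Small, fast parameterisations used across tests.

# A 16-position maze with the same segment proportions as the default model.
small_params <- function(...) {
  sim_params(n_inp = 16L, n = 16L, len = 16, t_choice = 10L,
             cue_zone = c(0, 4), stem = c(4, 10), branch = c(10, 16),
             t_plateau = 0:15, n_trials = 20L, ...)
}

small_preset <- function(n_trials = 10L, variant = "cue_dependent", ...) {
  experiment_preset(name = "small", task = task_spec(variant),
                    n_trials = n_trials, params = small_params(...))
}

# A 5-neuron instance for oracle comparisons.
tiny_params <- function(...) {
  sim_params(n_inp = 5L, n = 5L, len = 5, t_choice = 3L,
             cue_zone = c(0, 1), stem = c(1, 3), branch = c(3, 5),
             t_plateau = 0:4, clamp_steps = 1L, n_trials = 5L, ...)
}

# Shared cache so expensive runs are computed once per test session.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}
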