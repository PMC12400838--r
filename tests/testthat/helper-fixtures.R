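# Shared reduced fixtures. Tests use short protocols on a slightly coarser
# grid than the package defaults so the whole suite stays fast; the
# acceptance tests use resolutions close to the defaults.

fast_grid <- function() strain_grid(-0.4, 0.1, 201)

fast_config <- function(n_cycles = 10, ...) {
  protocol_config(n_cycles = n_cycles, grid = fast_grid(), dt = 1e-3, ...)
}

fast_activation <- function(n_cycles = 10) {
  gen_activation(synthetic_spec(n_cycles = n_cycles))
}

# metabolite state typical of late exercise, used for clamped runs
late_exercise_met <- function() {
  metabolite_state(ATP = 8.2, ADP = 0.03, Pi = 15, PCr = 5, pH = 7.0)
}
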