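# Small-network builders shared across the suite. Kernel widths are scaled
# up so a 20-neuron line still has smooth Gaussian rows.

tiny_spec <- function(n = 20) {
  connectivity_spec(N_E = n, N_I = n, sigma_E = 0.1, sigma_I = 0.12)
}

tiny_config <- function(n = 20, duration = 500, seed = 1, ...) {
  simulation_config(duration = duration, seed = seed,
                    connectivity = tiny_spec(n),
                    seizure = list(amplitude = 200, start = 50,
                                   duration = 200,
                                   targets = seq_len(max(2, n %/% 4))),
                    record_every_ms = 50, ...)
}

# drive a single pre/post spike pair through the plasticity operations and
# return the weight change of the (1, 1) synapse of Wp_EI
pair_update <- function(lag_ms, dt = 0.5, params = stdp_params()) {
  n_steps <- round(abs(lag_ms) / dt)
  ps <- init_plastic_state(2, 2)
  none <- c(FALSE, FALSE)
  first <- c(TRUE, FALSE)
  pre_first <- lag_ms > 0            # pre fires, then post after |lag|
  # spike 1
  ps <- stdp_weight_update(ps, if (pre_first) first else none,
                           if (pre_first) none else first, params)
  ps <- stdp_trace_step(ps, if (pre_first) first else none,
                        if (pre_first) none else first, params, dt)
  for (i in seq_len(n_steps - 1)) {
    ps <- stdp_weight_update(ps, none, none, params)
    ps <- stdp_trace_step(ps, none, none, params, dt)
  }
  # spike 2
  ps <- stdp_weight_update(ps, if (pre_first) none else first,
                           if (pre_first) first else none, params)
  ps$Wp_EI[1, 1] - 1
}
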