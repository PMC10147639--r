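# Reference integrator written independently of the compiled core: a plain
# R Heun step (drift and diffusion both averaged) used to cross-check the
# compiled path on short noise-free trajectories.
r_heun_steps <- function(state, currents, config, n_steps) {
  th <- state$phases
  for (s in seq_len(n_steps)) {
    a1 <- phase_drift(state, currents, config)
    pred <- state
    pred$phases <- wrap_phase(th + a1 * config$dt)
    a2 <- phase_drift(pred, currents, config)
    th <- th + 0.5 * (a1 + a2) * config$dt
    th <- wrap_phase(th)
    state$phases <- th
  }
  state
}

# small fully specified E/I state for deterministic tests
tiny_ei_state <- function(N = 6, n_inh = 2, seed = 42) {
  set.seed(seed)
  init_network(N, n_inh, "ei", sim_config())
}

# inter-spike intervals of the first neuron of a raster
first_neuron_isi <- function(raster) {
  diff(raster$time[raster$neuron == 1L])
}
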