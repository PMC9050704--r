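# Shared, lazily built objects so the expensive full-network runs happen once
# per test session. Everything is deterministic (the model has no noise
# source), so caching cannot leak state between tests.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

get_model <- function() cached("model", calibrate_model())

get_default_run <- function() cached("default_run", {
  m <- get_model()
  simulate_network(m$network, stimulus_spec(), dt = m$dt)
})

# neuron index sitting at u = 2.5 mm on the default grid (0.025 mm spacing)
N_CENTER <- 101L

get_spatial_t15 <- function() cached("spatial_t15", {
  run_spatial_experiment(get_model(), sites = 15)
})

get_main_sequence <- function() cached("main_sequence", {
  run_main_sequence(get_model())
})

get_temporal_i <- function() cached("temporal_i", {
  suppressWarnings(
    run_temporal_experiment(get_model(), "fixed_output_spikes", sites = 15))
})
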