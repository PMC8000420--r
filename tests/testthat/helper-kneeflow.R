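# Shared fixtures, built in code.

default_schedule <- function(duration = 48) {
  bounds <- default_sampling_times()
  build_stepwise_schedule(drainage_trendline(),
                          boundaries = bounds[bounds <= duration],
                          duration = duration)
}

# Simulate one study arm under the default schedule.
sim_arm <- function(arm, solver_step_min = 0.1, duration = 48,
                    volume = 75) {
  cfg <- reactor_config(default_depots(arm), default_schedule(duration),
                        volume = volume, duration = duration,
                        solver_step_min = solver_step_min, arm = arm)
  simulate_reactor(cfg)
}

# Noise-free measured dataset for all three arms (deterministic).
noise_free_fixture <- function(arms = arm_names()) {
  generate_arm_fixtures(arms = arms, n_replicates = 1, seed = 1,
                        meas = measurement_model(noise_sigma = 0))
}

# A single-depot reactor config with a custom release model, constant flow.
single_depot_config <- function(model, flow_ml_min, volume = 75,
                                duration = 48, solver_step_min = 0.1,
                                antibiotic = "vancomycin") {
  depots <- list(list(
    spec = depot_spec("csb", stats::setNames(model$total_mass, antibiotic)),
    models = stats::setNames(list(model), antibiotic)))
  reactor_config(depots, constant_schedule(flow_ml_min, duration),
                 volume = volume, duration = duration,
                 solver_step_min = solver_step_min)
}
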