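# Shared fixtures: baseline setups and a constructor for synthetic
# trajectories used to test metrics against analytic curves.

base_p <- baseline_parameters()
ic_iv <- baseline_initial_conditions("intravenous", "cold", 1e6, 1e6)
ic_it <- baseline_initial_conditions("intratumoral", "cold", 1e6, 1e6)
ic_untreated <- baseline_initial_conditions("intravenous", "cold", 1e6, 0)

# Coarser grid for tests that only need qualitative trajectories.
coarse <- simulation_settings(output_step = 0.05)

# Build a "trajectory" object from an arbitrary time grid and one focal
# variable (other states zero unless supplied), bypassing the integrator.
synthetic_trajectory <- function(times, values = NULL, states = NULL,
                                 params = base_p) {
  if (is.null(states)) {
    states <- matrix(0, length(times), 8,
                     dimnames = list(NULL, state_names()))
  }
  if (!is.null(values)) {
    for (nm in names(values)) states[, nm] <- values[[nm]]
  }
  structure(list(times = times, states = states, params = params,
                 settings = simulation_settings(t_end = max(times)),
                 diagnostics = list()),
            class = "trajectory")
}
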