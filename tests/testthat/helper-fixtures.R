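# Shared fixtures. Heavy mixture fits are cached so that module tests and
# the acceptance suite reuse the same simulated data sets and fits.

.fixture_cache <- new.env(parent = emptyenv())

default_protocol <- function() ramp_protocol()
default_polymer <- function() polymer_params()

# simulate a scenario and fit a K-component mixture, cached by key
scenario_fit <- function(name, K, n_cycles = 5000, sim_seed = 7,
                         fit_seed = 1, n_starts = 10) {
  key <- paste(name, K, n_cycles, sim_seed, fit_seed, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sc <- load_scenario(name)
  cyc <- simulate_cycles(sc$mixture, sc$protocol, sc$polymer, sc$noise,
                         n_cycles, seed = sim_seed)
  forces <- cyc$force[cyc$ruptured]
  fit <- fit_bell_mixture(forces, sum(!cyc$ruptured), sc$protocol, K,
                          n_starts = n_starts, seed = fit_seed)
  out <- list(scenario = sc, cycles = cyc, forces = forces, fit = fit)
  .fixture_cache[[key]] <- out
  out
}

# canonical hold-time design for folding-kinetics recovery: early points
# resolve the rate, late points anchor the plateau
pfold_hold_times <- function() c(3, 6, 9, 30, 50, 60)
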