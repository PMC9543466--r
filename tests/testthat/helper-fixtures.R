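# Shared, lazily built simulation fixtures so several test files can reuse
# one reduced scenario sweep instead of re-running it.
.fixture_cache <- new.env(parent = emptyenv())

reduced_grid_records <- function() {
  if (is.null(.fixture_cache$rec)) {
    g <- scenario_grid(offtake_values = seq(0, 5000, by = 500),
                       phi_values = seq(0.60, 0.84, by = 0.04),
                       replicates = 40, base_seed = 42)
    .fixture_cache$rec <- run_grid(g, demographic_params())
  }
  .fixture_cache$rec
}

# Noiseless metrics table with a prescribed response over a grid; mimics
# the run_grid() column layout.
synthetic_records <- function(f, offtake_values = seq(0, 5000, by = 250),
                              phi_values = seq(0.6, 0.84, by = 0.04),
                              replicates = 3) {
  scen <- expand.grid(offtake = offtake_values, phi = phi_values,
                      replicate = seq_len(replicates))
  scen$growth_total <- f(scen$offtake, scen$phi)
  scen$mean_annual_growth <- scen$growth_total / 20
  scen$extinct <- scen$growth_total <= -1
  scen
}

# Minimal respondent table for estimator simulations where only the
# latent hunting status matters.
minimal_profiles <- function(n, hunt_prob) {
  data.frame(respondent_id = seq_len(n),
             site_id = rep_len(1:46, n),
             hunts_geese = stats::runif(n) < hunt_prob)
}
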