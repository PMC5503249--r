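# Shared fixtures, built once per test run.

fx <- load_fixture_model()

# steady states of the packaged parameterization, cached
fx_ss <- list(`70` = steady_state(fx$model70),
              `80` = steady_state(fx$model80))

# a quick deterministic synthetic ground truth with exact Van't Hoff
# pairing (no jitter), reused by estimation and synthetic-data tests
gt0 <- generate_ground_truth(seed = 101,
                             config = list(vant_hoff_sdlog = 0))

# minimal stand-in steady-state object for comparison arithmetic
fake_ss <- function(conc, fluxes = NULL) {
  structure(list(concentrations = conc, fluxes = fluxes,
                 converged = TRUE, final_time = 0,
                 max_residual_rate = 0),
            class = "ed_steady_state")
}
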