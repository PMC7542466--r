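# shared small fixtures: a 6-layer, 2000 m column and a fast run config

small_grid <- function() column_grid(c(50, 80, 170, 300, 600, 800))

# a few years at desk scale; enough for plastic to enter every pathway
small_config <- function(params = "test_med", years = c(1950, 1955),
                         spinup_years = 3, ...) {
  run_config(params = params, grid = small_grid(), years = years,
             spinup_years = spinup_years, ...)
}

# a productive mid-step ecosystem state used by rate-level tests
busy_state <- function(grid = small_grid()) {
  tracer_state(grid, N = 5, PH = 0.4, CO = 0.3, DZ = 0.05, Z = 0.3,
               DET_A = 0.2, DET_Z = 0.1, MP = 10, MP_A = 4, MP_Z = 2)
}
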