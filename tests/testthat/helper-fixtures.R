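# Shared fixtures, built lazily and memoised across test files. Everything
# is generated in code at test time; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_geom <- function() fixture("geom", capillary_geometry)
fx_laser <- function() fixture("laser", laser_source)
fx_medium <- function() fixture("medium", medium_water)
fx_grid <- function() fixture("grid", function() make_grid(fx_geom()))
fx_source <- function() fixture("source", function() {
  heat_source_field(fx_laser(), fx_geom(), fx_grid())
})
fx_steady <- function() fixture("steady", function() {
  solve_steady_temperature(fx_medium(), fx_source(), fx_geom(), fx_grid())
})

# Dense early snapshots for establishment analysis (laser on at t = 0).
fx_establishment_series <- function() fixture("est_series", function() {
  solve_transient_temperature(fx_medium(), fx_source(), fx_geom(), fx_grid(),
                              times = seq(0, 1.5, by = 0.01),
                              laser_on = 0, laser_off = 20)
})

# Coarse snapshots covering the full 20 s on-phase for transport solves.
fx_temp_series <- function() fixture("temp_series", function() {
  solve_transient_temperature(fx_medium(), fx_source(), fx_geom(), fx_grid(),
                              times = c(seq(0, 1.5, by = 0.05), 20),
                              laser_on = 0, laser_off = 20)
})

# A stationary (frozen steady-state) series for closed-form steady checks.
fx_frozen_series <- function() fixture("frozen_series", function() {
  tser <- fx_temp_series()
  structure(
    list(times = 0, fields = array(tser$steady, c(fx_grid()$nr, fx_grid()$nz, 1)),
         steady = tser$steady, grid = fx_grid(), laser_on = 0, laser_off = Inf,
         ambient = fx_medium()$ambient_temperature, focus = tser$focus),
    class = "temperature_series"
  )
})

fx_times <- function() seq(0, 20, by = 0.1)

# The workhorse Conc(t) library: 21 S_T points spanning [-2.5, 2.5] 1/K on
# the default grid with the default 2-D circle probe.
fx_library <- function() fixture("library", function() {
  build_conc_library(seq(-2.5, 2.5, length.out = 21), transport_params(),
                     fx_temp_series(), fx_grid(),
                     region = probe_region("circle"), times = fx_times())
})

fx_conc_series <- function(soret, times = fx_times()) {
  solve_drift_diffusion(transport_params(soret_ST = soret), fx_temp_series(),
                        fx_grid(), times)
}

# Noiseless stage-1/stage-2 synthetic pair at given truth.
fx_particle_trace <- function(soret, seed = 1, noise = 0, k = -0.22) {
  generate_particle_trace(
    trace_recipe("particle", soret_ST = soret, decay_rate_k = k,
                 noise_sigma = noise, seed = seed),
    fx_library()
  )
}
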