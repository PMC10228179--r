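# Convenience layer tying the heat solve, transport solve and library build
# together from a run configuration. Used by the command-line interface and
# by reproducible analysis scripts.

#' Simulate the laser-heating temperature series for a configuration
#'
#' Runs the transient heat solve with snapshots dense enough for the
#' establishment analysis over the first ~1.5 s, then sparse (the field has
#' converged to the steady profile well before that).
#'
#' @param config A `run_config`.
#' @param times Optional snapshot times, s; defaults to a dense/sparse split
#'   suited to the on-phase `[on_s, off_s]`.
#' @return A `temperature_series`.
#' @export
simulate_temperature <- function(config = default_run_config(), times = NULL) {
  obj <- config_objects(config)
  on <- config$times$on_s; off <- config$times$off_s
  if (is.null(times)) {
    times <- unique(c(seq(on, min(on + 1.5, off), by = 0.05), off))
  }
  q <- heat_source_field(obj$laser, obj$geom, obj$grid)
  solve_transient_temperature(obj$medium, q, obj$geom, obj$grid, times,
                              laser_on = on, laser_off = off)
}

#' Build the Conc(t) library for a configuration
#'
#' @param config A `run_config` (the `fit` section sets the S_T grid).
#' @param soret_grid Optional explicit S_T grid, 1/K; defaults to the
#'   configured uniform grid.
#' @param temperature Optional precomputed `temperature_series`.
#' @param cache_dir Optional cache directory (see [build_conc_library()]).
#' @param quiet Suppress progress output.
#' @return A `conc_library`.
#' @export
soret_library <- function(config = default_run_config(), soret_grid = NULL,
                          temperature = NULL, cache_dir = NULL, quiet = TRUE) {
  obj <- config_objects(config)
  if (is.null(soret_grid)) {
    soret_grid <- seq(config$fit$soret_min_per_K, config$fit$soret_max_per_K,
                      length.out = config$fit$soret_points)
  }
  if (is.null(temperature)) temperature <- simulate_temperature(config)
  times <- seq(0, config$times$off_s - config$times$on_s,
               by = config$times$dt_s)
  build_conc_library(soret_grid, obj$params, temperature, obj$grid,
                     region = obj$region, times = times,
                     cache_dir = cache_dir, quiet = quiet)
}

#' Export a temperature field as a tabular node list
#'
#' @param field Temperature matrix from [solve_steady_temperature()] (or one
#'   snapshot of a series).
#' @param grid The `fv_grid` it lives on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, grid, path) {
  df <- data.frame(
    r_m = rep(grid$r, times = grid$nz),
    z_m = rep(grid$z, each = grid$nr),
    value = as.vector(field)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
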