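# Trace CSV dialect and run configuration.
#
# Trace files: header row with columns time_s, intensity, trace_id, role
# (any column order, extra columns preserved as metadata-free). Laser
# switching times travel in a YAML sidecar (<stem>.meta.yaml) written by
# write_traces(), or are supplied explicitly to read_traces().

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

#' Write MST traces to CSV (plus a YAML sidecar)
#'
#' All traces are stacked into one CSV with columns `time_s, intensity,
#' trace_id, role`; per-trace laser markers and metadata go into a
#' `<stem>.meta.yaml` sidecar so the round trip through [read_traces()] is
#' lossless.
#'
#' @param traces An [mst_trace()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "mst_trace")) traces <- list(traces)
  check_that(length(traces) >= 1, "no traces to write")
  ids <- vapply(traces, function(tr) tr$trace_id, "")
  check_that(!anyDuplicated(ids), "trace_id values must be unique within a file")
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$times, intensity = tr$intensities,
               trace_id = tr$trace_id, role = tr$role)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- lapply(traces, function(tr) {
    list(laser_on_s = tr$laser_on, laser_off_s = tr$laser_off,
         metadata = tr$metadata)
  })
  names(meta) <- ids
  yaml::write_yaml(list(traces = meta), sidecar_path(path))
  invisible(path)
}

#' Read MST traces from CSV
#'
#' @param path CSV with columns `time_s, intensity, trace_id, role` (any
#'   order; matched by header). Malformed rows are reported with their line
#'   numbers.
#' @param laser_on,laser_off Laser markers, s, applied to every trace when
#'   no sidecar is present (the sidecar takes precedence).
#' @return List of [mst_trace()] objects (in file order of first appearance).
#' @export
read_traces <- function(path, laser_on = NULL, laser_off = NULL) {
  check_that(file.exists(path), "trace file not found: %s", path)
  df <- utils::read.csv(path, check.names = TRUE, colClasses = NA)
  required <- c("time_s", "intensity", "trace_id", "role")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_soret("trace file %s is missing required column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  tvals <- suppressWarnings(as.numeric(df$time_s))
  ivals <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(!is.finite(tvals) | !is.finite(ivals))
  if (length(bad)) {
    stop_soret("malformed row(s) in %s (non-numeric time or intensity) at line(s): %s",
               path, paste(bad + 1L, collapse = ", "))   # +1 for header line
  }
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- yaml::read_yaml(sp)$traces
  ids <- unique(df$trace_id)
  lapply(ids, function(id) {
    rows <- df$trace_id == id
    tt <- tvals[rows]
    if (any(diff(tt) <= 0)) {
      ln <- which(rows)[which(diff(tt) <= 0)[1] + 1L] + 1L
      stop_soret("non-monotone time column for trace '%s' in %s (line %d)",
                 id, path, ln)
    }
    m <- meta[[id]]
    on <- if (!is.null(m)) m$laser_on_s else laser_on
    off <- if (!is.null(m)) m$laser_off_s else laser_off
    check_that(!is.null(on) && !is.null(off),
               "no laser_on/laser_off available for trace '%s': supply them or provide the sidecar %s",
               id, sp)
    mst_trace(tt, ivals[rows], on, off, trace_id = id,
              role = df$role[rows][1],
              metadata = if (!is.null(m)) m$metadata else list())
  })
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' Nested configuration mirroring the module parameters, with unit suffixes
#' in every key name. Every default is either an instrument/printed value
#' (laser power, absorption, geometry, diffusion coefficient, probe size)
#' or a documented modelling choice (ambient temperature, grid, noise).
#'
#' @return Nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(capillary_radius_m = 2e-4, axial_half_length_m = 2e-4),
    laser = list(power_W = 0.05, reflection = 0.05, absorption_per_m = 50,
                 beam_diameter_m = 1e-5),
    medium = list(ambient_K = 293.15, k_W_per_m_K = 0.6, rho_kg_per_m3 = 998,
                  cp_J_per_kg_K = 4182),
    transport = list(diffusion_D_m2_per_s = 2.25e-12,
                     initial_concentration_mol_per_m3 = 1),
    grid = list(refine = 1),
    probe = list(kind = "circle", planar_diameter_m = 1.3e-4,
                 thickness_m = 2e-5),
    fit = list(soret_min_per_K = -2.5, soret_max_per_K = 2.5,
               soret_points = 51, qc_threshold = 5),
    times = list(on_s = 0, off_s = 20, dt_s = 0.1),
    synthetic = list(background_counts = 200, amplitude_counts = 800,
                     decay_rate_per_s = -0.22, noise_sigma = 0,
                     n_points = 601, duration_s = 30, laser_on_s = 5,
                     laser_off_s = 25, seed = 1)
  ), class = "run_config")
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      stop_soret("unknown configuration key: %s", paste(here, collapse = "$"))
    }
    if (is.list(base[[key]])) {
      check_that(is.list(override[[key]]),
                 "configuration section %s must be a mapping", paste(here, collapse = "$"))
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read and validate a run configuration
#'
#' Reads a YAML file, validates it against the [default_run_config()]
#' skeleton (unknown keys are rejected), and fills unspecified entries with
#' the defaults.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  check_that(file.exists(path), "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  structure(merge_config(unclass(cfg), user), class = "run_config")
}

#' Assemble the physical model objects described by a configuration
#'
#' @param config A `run_config`.
#' @return List with `geom`, `laser`, `medium`, `grid`, `params`, `region`.
#' @export
config_objects <- function(config = default_run_config()) {
  geom <- capillary_geometry(config$geometry$capillary_radius_m,
                             config$geometry$axial_half_length_m)
  list(
    geom = geom,
    laser = laser_source(config$laser$power_W, config$laser$reflection,
                         config$laser$absorption_per_m,
                         config$laser$beam_diameter_m),
    medium = medium_water(config$medium$k_W_per_m_K, config$medium$rho_kg_per_m3,
                          config$medium$cp_J_per_kg_K, config$medium$ambient_K),
    grid = make_grid(geom, refine = config$grid$refine),
    params = transport_params(config$transport$diffusion_D_m2_per_s,
                              initial_concentration =
                                config$transport$initial_concentration_mol_per_m3),
    region = probe_region(config$probe$kind, config$probe$planar_diameter_m,
                          config$probe$thickness_m)
  )
}
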