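# Thermophoretic drift-diffusion solver. The particle flux is
#   J = -D grad(c) - c D_T grad(T),   D_T = D * S_T,
# discretized with a conservative finite-volume scheme whose face fluxes use
# Scharfetter-Gummel exponential fitting: the drift-diffusion analogue of
# central differencing that stays positivity-preserving at any cell Peclet
# number and reproduces the Boltzmann steady state c ~ exp(-S_T (T - T_ref))
# exactly on the discrete level.

#' Particle transport parameters
#'
#' @param diffusion_D Particle diffusion coefficient, m^2/s
#'   (default 2.25e-12, polystyrene nanoparticles in water).
#' @param soret_ST Soret coefficient S_T, 1/K (signed; positive =
#'   thermophobic, depletes from the hot focus).
#' @param initial_concentration Uniform initial concentration, mol/m^3.
#' @return Object of class `transport_params`; the thermal diffusion
#'   coefficient `thermal_diffusion_DT = diffusion_D * soret_ST` is derived.
#' @export
#' @examples
#' transport_params(soret_ST = 0.07)
transport_params <- function(diffusion_D = 2.25e-12, soret_ST = 0,
                             initial_concentration = 1) {
  check_that(diffusion_D > 0, "diffusion_D must be > 0 (m^2/s)")
  check_that(is.numeric(soret_ST) && length(soret_ST) == 1 && is.finite(soret_ST),
             "soret_ST must be a finite number (1/K)")
  check_that(initial_concentration > 0, "initial_concentration must be > 0")
  structure(
    list(diffusion_D = diffusion_D, soret_ST = soret_ST,
         thermal_diffusion_DT = diffusion_D * soret_ST,
         initial_concentration = initial_concentration),
    class = "transport_params"
  )
}

# Drift-diffusion operator M (so that V dc/dt = -M c) for a frozen
# temperature field, with no-flux outer boundaries. Scharfetter-Gummel face
# fluxes; Pe_ij = S_T (T_i - T_j) is the face Peclet number of the
# thermophoretic drift.
transport_matrix <- function(params, Tfield, grid) {
  D <- params$diffusion_D
  Tv <- as.vector(Tfield)
  fi <- grid$face_from; fj <- grid$face_to
  g0 <- D * grid$face_Ah
  Pe <- params$soret_ST * (Tv[fi] - Tv[fj])
  bi <- bernoulli_fn(-Pe)   # coefficient on c_i in the i -> j flux
  bj <- bernoulli_fn(Pe)    # coefficient on c_j
  n <- grid$nr * grid$nz
  Matrix::sparseMatrix(
    i = c(fi, fi, fj, fj),
    j = c(fi, fj, fj, fi),
    x = c(g0 * bi, -g0 * bj, g0 * bj, -g0 * bi),
    dims = c(n, n)
  )
}

#' Solve the thermophoretic drift-diffusion equation
#'
#' Implicit-Euler finite-volume integration of `dc/dt = -div(J)` with
#' `J = -D grad(c) - c D_T grad(T)` and no-flux outer boundaries, starting
#' from a uniform concentration. The temperature is taken from the snapshot
#' of `temperature` in force at the end of each step (one-way coupling:
#' heat establishes in under a second, mass transport runs for tens of
#' seconds). Total mass is conserved to linear-solver roundoff.
#'
#' @param params A [transport_params()].
#' @param temperature A `temperature_series` whose snapshots cover `times`,
#'   on the same grid.
#' @param grid The `fv_grid` shared with the heat solve.
#' @param times Strictly increasing output times, s; `times[1]` is the
#'   initial condition (uniform concentration). Steps are taken directly
#'   between consecutive output times.
#' @return Object of class `concentration_series`: `times` and a 3-D array
#'   `fields` (`nr` x `nz` x time) of concentration, mol/m^3.
#' @export
solve_drift_diffusion <- function(params, temperature, grid, times) {
  check_that(inherits(params, "transport_params"), "params must be transport_params")
  check_that(inherits(temperature, "temperature_series"),
             "temperature must be a temperature_series")
  check_that(all(diff(times) > 0), "times must be strictly increasing")
  check_that(identical(dim(temperature$fields)[1:2], c(grid$nr, grid$nz)),
             "temperature series grid does not match the transport grid")
  # The last snapshot is held constant beyond the stored times. That is only
  # sound while no laser switching event remains uncovered: either the series
  # extends past laser_off, or the laser is still on at the end of the run
  # (the late fields have converged to the steady profile).
  tmax <- max(temperature$times)
  if (max(times) > tmax + 1e-9) {
    check_that(temperature$laser_off > max(times) ||
                 tmax >= temperature$laser_off,
               paste0("temperature series (up to %.4g s) does not cover the ",
                      "laser-off transient needed for times up to %.4g s"),
               tmax, max(times))
  }

  n <- grid$nr * grid$nz
  V <- as.vector(grid$vol)
  c_now <- rep(params$initial_concentration, n)
  fields <- array(NA_real_, dim = c(grid$nr, grid$nz, length(times)))
  fields[, , 1] <- c_now

  # snapshot in force at the end of each step (last snapshot at or before t)
  snap_idx <- findInterval(times[-1] + 1e-12, temperature$times)
  snap_idx[snap_idx < 1L] <- 1L
  last_key <- NULL
  fact <- NULL
  for (s in seq_along(snap_idx)) {
    dt <- times[s + 1L] - times[s]
    key <- sprintf("%d|%.12g", snap_idx[s], dt)
    if (!identical(key, last_key)) {
      M <- transport_matrix(params, temperature$fields[, , snap_idx[s]], grid)
      fact <- Matrix::lu(M + Matrix::Diagonal(x = V / dt))
      last_key <- key
    }
    c_now <- as.vector(Matrix::solve(fact, V / dt * c_now))
    if (!all(is.finite(c_now))) {
      stop_soret("drift-diffusion solve produced non-finite values at t = %.4g s",
                 times[s + 1L])
    }
    if (min(c_now) < -1e-9 * params$initial_concentration) {
      Tv <- as.vector(temperature$fields[, , snap_idx[s]])
      pe_max <- max(abs(params$soret_ST * (Tv[grid$face_from] - Tv[grid$face_to])))
      stop_soret(paste0(
        "negative concentrations beyond tolerance at t = %.4g s ",
        "(min %.3g); max cell Peclet %.3g - refine the grid near the focus"),
        times[s + 1L], min(c_now), pe_max)
    }
    fields[, , s + 1L] <- c_now
  }
  structure(
    list(times = times, fields = fields, grid = grid, params = params),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  m0 <- sum(x$fields[, , 1] * x$grid$vol)
  mN <- sum(x$fields[, , dim(x$fields)[3]] * x$grid$vol)
  cat(sprintf("Concentration series: %d snapshots over [%.3g, %.3g] s, S_T = %.4g 1/K\n",
              length(x$times), min(x$times), max(x$times), x$params$soret_ST))
  cat(sprintf("  mass drift: %.3g relative; focal depletion at end: %.4g\n",
              abs(mN - m0) / m0,
              1 - x$fields[1, which.min(abs(x$grid$z)), dim(x$fields)[3]] /
                x$fields[1, which.min(abs(x$grid$z)), 1]))
  invisible(x)
}

#' Optical probe region
#'
#' Region over which the concentration field is averaged to form the
#' observable Conc(t): a disk-shaped volume (3-D), a circle in the focal
#' plane (2-D), or a radial line (1-D), all centred on the laser focus.
#'
#' @param kind `"disk"`, `"circle"` or `"line"`.
#' @param planar_diameter In-plane diameter (or line length), m.
#' @param thickness Disk thickness, m (disk only).
#' @return Object of class `probe_region`.
#' @export
#' @examples
#' probe_region("disk")                      # 130 um x 20 um disk
#' probe_region("circle")                    # 130 um diameter focal circle
probe_region <- function(kind = c("circle", "disk", "line"),
                         planar_diameter = 1.3e-4,
                         thickness = if (kind[1] == "disk") 2e-5 else 0) {
  kind <- match.arg(kind)
  check_that(planar_diameter > 0, "planar_diameter must be > 0 (m)")
  if (kind == "disk") check_that(thickness > 0, "disk thickness must be > 0 (m)")
  structure(
    list(kind = kind, planar_diameter = planar_diameter, thickness = thickness),
    class = "probe_region"
  )
}

# Node weights implementing the probe-region average on a grid.
probe_weights <- function(region, grid) {
  rad <- region$planar_diameter / 2
  check_that(rad <= max(grid$r) + 1e-15,
             "probe region (radius %.3g m) exceeds the domain (radius %.3g m)",
             rad, max(grid$r))
  w <- matrix(0, grid$nr, grid$nz)
  j0 <- which.min(abs(grid$z))
  in_r <- grid$r <= rad + 1e-15
  if (region$kind == "circle") {
    w[in_r, j0] <- grid$a_r[in_r]
  } else if (region$kind == "line") {
    w[in_r, j0] <- diff(grid$rf)[in_r]
  } else { # disk
    half <- region$thickness / 2
    check_that(half <= max(grid$z) + 1e-15,
               "probe disk thickness exceeds the domain axial extent")
    in_z <- abs(grid$z) <= half + 1e-15
    w[in_r, in_z] <- outer(grid$a_r[in_r], grid$dzc[in_z])
  }
  w / sum(w)
}

#' Reduce a concentration series to the normalized probe curve Conc(t)
#'
#' Mean concentration over the probe region at each time, normalized by its
#' value at the first stored time (laser-on), so `Conc(0) = 1`.
#'
#' @param series A `concentration_series`.
#' @param region A [probe_region()].
#' @return Object of class `conc_curve` with fields `times` and `values`.
#' @export
reduce_to_conc_curve <- function(series, region = probe_region()) {
  check_that(inherits(series, "concentration_series"),
             "series must be a concentration_series")
  check_that(inherits(region, "probe_region"), "region must be a probe_region")
  w <- probe_weights(region, series$grid)
  nt <- dim(series$fields)[3]
  vals <- vapply(seq_len(nt), function(k) sum(series$fields[, , k] * w), 0)
  check_that(vals[1] > 0, "probe mean at t = 0 is not positive")
  conc_curve(series$times, vals / vals[1],
             soret = series$params$soret_ST, region = region)
}

#' Construct a Conc(t) curve
#'
#' @param times Times, s (re-zeroed at laser-on).
#' @param values Normalized probe-mean concentrations; `values[1]` must be 1.
#' @param soret Optional S_T the curve corresponds to, 1/K.
#' @param region Optional [probe_region()] provenance.
#' @return Object of class `conc_curve`.
#' @export
conc_curve <- function(times, values, soret = NA_real_, region = NULL) {
  check_that(length(times) == length(values), "times and values differ in length")
  check_that(abs(values[1] - 1) < 1e-12, "Conc(t) must be normalized: values[1] = 1")
  check_that(all(values > 0), "Conc(t) values must be positive")
  structure(
    list(times = times, values = values, soret = soret, region = region),
    class = "conc_curve"
  )
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("Conc(t) curve: %d samples over [%.3g, %.3g] s%s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.finite(x$soret)) sprintf(", S_T = %.4g 1/K", x$soret) else ""))
  cat(sprintf("  depletion depth 1 - min Conc: %.4g\n", 1 - min(x$values)))
  invisible(x)
}
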