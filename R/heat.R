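# Laser-heating solver: volumetric source, steady conduction, and transient
# conduction on the axisymmetric grid. Replaces the finite-element heat
# transfer stage of the forward model with a conservative finite-volume solve.

#' Laser heat-load field
#'
#' Volumetric power density q(r, z) (W/m^3) deposited by the IR laser: a
#' Gaussian transverse profile of width `sigma_x = sigma_y` centred on the
#' focus, attenuated along z by Beer-Lambert absorption
#' `exp(-Ac (z + L))` where `L` is the axial half-length. The field is
#' normalized so that its discrete volume integral equals the absorbed power
#' `Q0 (1 - Rc) (1 - exp(-Ac * 2L))`.
#'
#' @param laser A [laser_source()].
#' @param geom A [capillary_geometry()].
#' @param grid An `fv_grid` covering the domain.
#' @return Matrix (`nr` x `nz`) of power density, W/m^3, with attribute
#'   `absorbed_power` (W).
#' @export
#' @examples
#' g <- make_grid()
#' q <- heat_source_field(laser_source(), capillary_geometry(), g)
#' attr(q, "absorbed_power")    # ~9.4e-4 W at the default settings
heat_source_field <- function(laser, geom, grid) {
  check_that(inherits(laser, "laser_source"), "laser must be a laser_source")
  check_that(inherits(grid, "fv_grid"), "grid must be an fv_grid")
  sigma <- laser$sigma_x
  n_waist <- sum(grid$r <= 2 * sigma)
  if (n_waist < 4) {
    stop_soret(paste0(
      "grid does not resolve the beam waist: only %d radial node(s) inside ",
      "2 sigma = %.3g m; refine the radial spacing near the axis"), n_waist,
      2 * sigma)
  }
  L <- geom$axial_half_length
  absorbed <- laser$power_Q0 * (1 - laser$reflection_Rc) *
    (1 - exp(-laser$absorption_Ac * 2 * L))
  shape <- outer(
    exp(-(grid$r - laser$focus_r0)^2 / (2 * sigma^2)),
    exp(-laser$absorption_Ac * (grid$z - laser$focus_z0 + L))
  )
  total <- sum(shape * grid$vol)
  q <- if (absorbed > 0) shape * (absorbed / total) else shape * 0
  attr(q, "absorbed_power") <- absorbed
  q
}

# Sparse conduction matrix K (W/K) over all nodes: K %*% T gives the net
# conductive outflow per node. Symmetric positive semi-definite.
conduction_matrix <- function(medium, grid) {
  g <- medium$thermal_conductivity * grid$face_Ah
  i <- c(grid$face_from, grid$face_to, grid$face_from, grid$face_to)
  j <- c(grid$face_from, grid$face_to, grid$face_to, grid$face_from)
  x <- c(g, g, -g, -g)
  n <- grid$nr * grid$nz
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Steady-state temperature field
#'
#' Solves the discrete conduction balance `k lap(T) + q = 0` with Dirichlet
#' ambient temperature on the capillary wall and both axial ends, and the
#' symmetry condition on the axis.
#'
#' @param medium A [medium_water()].
#' @param source Source field from [heat_source_field()], W/m^3.
#' @param geom A [capillary_geometry()].
#' @param grid The `fv_grid` the source was computed on.
#' @return Matrix (`nr` x `nz`) of absolute temperature, K.
#' @export
solve_steady_temperature <- function(medium, source, geom, grid) {
  check_that(inherits(medium, "medium"), "medium must be a medium object")
  n <- grid$nr * grid$nz
  check_that(length(source) == n, "source field does not match the grid")
  K <- conduction_matrix(medium, grid)
  interior <- which(!as.vector(grid$boundary))
  A <- K[interior, interior, drop = FALSE]
  b <- as.vector(source * grid$vol)[interior]
  theta_i <- tryCatch(
    as.vector(Matrix::solve(A, b)),
    error = function(e) stop_soret(
      "steady conduction system is singular or ill-conditioned (%s); check the grid for zero spacings or a degenerate domain",
      conditionMessage(e))
  )
  if (!all(is.finite(theta_i))) {
    stop_soret("steady conduction solve produced non-finite temperatures; the grid is pathological")
  }
  theta <- numeric(n)
  theta[interior] <- theta_i
  matrix(medium$ambient_temperature + theta, grid$nr, grid$nz)
}

#' Transient temperature series
#'
#' Implicit-Euler integration of `rho cp dT/dt = k lap(T) + q(t)` with the
#' laser switched on over `[laser_on, laser_off]`. The temperature starts at
#' ambient, converges to the steady solution while the laser is on, and
#' relaxes back to ambient after switch-off. Fields are stored at the
#' requested `times`; internal stepping uses `dt_fine` for the first second
#' after each switching event and `dt_coarse` elsewhere.
#'
#' @inheritParams solve_steady_temperature
#' @param times Strictly increasing snapshot times, s (simulation clock).
#' @param laser_on,laser_off Laser switching times, s.
#' @param dt_fine,dt_coarse Internal time-step sizes, s.
#' @return An object of class `temperature_series`: snapshot `times`, a
#'   3-D array `fields` (`nr` x `nz` x time), the `steady` laser-on field,
#'   the grid, and the focus node index.
#' @export
solve_transient_temperature <- function(medium, source, geom, grid, times,
                                        laser_on = 0, laser_off = Inf,
                                        dt_fine = 0.01, dt_coarse = 0.05) {
  check_that(all(diff(times) > 0), "times must be strictly increasing")
  check_that(laser_on < laser_off, "laser_on must precede laser_off")
  n <- grid$nr * grid$nz
  K <- conduction_matrix(medium, grid)
  interior <- which(!as.vector(grid$boundary))
  A <- K[interior, interior, drop = FALSE]
  cap <- (medium$density * medium$heat_capacity * as.vector(grid$vol))[interior]
  b_src <- as.vector(source * grid$vol)[interior]

  # Internal step times: requested snapshots plus a fine/coarse ladder that
  # resolves the establishment transients after each switching event.
  t0 <- times[1]; t_end <- times[length(times)]
  ladder <- seq(t0, t_end, by = dt_coarse)
  for (ev in c(laser_on, laser_off)) {
    if (is.finite(ev) && ev < t_end) {
      fine_end <- min(ev + 1, t_end)
      ladder <- c(ladder, seq(max(ev, t0), fine_end, by = dt_fine))
    }
  }
  cand <- c(ladder, times,
            if (is.finite(laser_on)) laser_on,
            if (is.finite(laser_off)) laser_off)
  cand <- cand[cand >= t0 & cand <= t_end]
  steps <- sort(unique(round(cand, 9)))

  theta <- numeric(length(interior))   # rise above ambient, interior nodes
  fields <- array(NA_real_, dim = c(grid$nr, grid$nz, length(times)))
  full <- numeric(n)
  snap <- function(k) {
    full[interior] <<- theta
    fields[, , k] <<- medium$ambient_temperature + full
  }
  next_snap <- 1L
  if (abs(steps[1] - times[1]) < 1e-12) { snap(1L); next_snap <- 2L }

  fact_cache <- list()
  for (s in seq_len(length(steps) - 1L)) {
    dt <- steps[s + 1L] - steps[s]
    key <- sprintf("%.12g", dt)
    if (is.null(fact_cache[[key]])) {
      fact_cache[[key]] <- Matrix::Cholesky(
        A + Matrix::Diagonal(x = cap / dt), LDL = FALSE)
    }
    on_now <- steps[s + 1L] > laser_on && steps[s + 1L] <= laser_off
    rhs <- cap / dt * theta + if (on_now) b_src else 0
    theta <- as.vector(Matrix::solve(fact_cache[[key]], rhs, system = "A"))
    if (!all(is.finite(theta))) {
      stop_soret("transient heat solve produced non-finite values at t = %.4g s (step %d)",
                 steps[s + 1L], s)
    }
    while (next_snap <= length(times) &&
           abs(steps[s + 1L] - times[next_snap]) < 1e-9) {
      snap(next_snap)
      next_snap <- next_snap + 1L
    }
  }
  check_that(next_snap == length(times) + 1L,
             "internal stepping failed to hit all snapshot times")

  steady <- solve_steady_temperature(medium, source, geom, grid)
  structure(
    list(times = times, fields = fields, steady = steady, grid = grid,
         laser_on = laser_on, laser_off = laser_off,
         ambient = medium$ambient_temperature,
         focus = focus_index(grid)),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  fi <- x$focus
  rise <- x$fields[fi["i"], fi["j"], ] - x$ambient
  cat(sprintf("Temperature series: %d snapshots over [%.3g, %.3g] s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  focal rise: max %.3g K (steady %.3g K); laser on [%.3g, %.3g] s\n",
              max(rise), x$steady[fi["i"], fi["j"]] - x$ambient,
              x$laser_on, x$laser_off))
  invisible(x)
}

#' Temperature-gradient establishment time
#'
#' Earliest time after laser-on at which the focal-point temperature rise
#' first reaches `fraction` of its steady-state value, with linear
#' interpolation between stored snapshots.
#'
#' @param series A `temperature_series` covering the laser-on segment.
#' @param fraction Threshold fraction of the steady-state rise, in \[0, 1).
#' @return Establishment time in seconds (measured from laser-on).
#' @export
gradient_establishment_time <- function(series, fraction = 0.99) {
  check_that(inherits(series, "temperature_series"),
             "series must be a temperature_series")
  check_that(fraction >= 0 && fraction < 1, "fraction must be in [0, 1)")
  if (fraction == 0) return(0)
  fi <- series$focus
  rise <- series$fields[fi["i"], fi["j"], ] - series$ambient
  steady_rise <- series$steady[fi["i"], fi["j"]] - series$ambient
  check_that(steady_rise > 0, "steady-state focal rise is zero; no laser-on segment to analyse")
  sel <- series$times >= series$laser_on
  check_that(any(sel), "series has no samples after laser_on")
  tt <- series$times[sel] - series$laser_on
  rr <- rise[sel] / steady_rise
  hit <- which(rr >= fraction)
  if (!length(hit)) {
    stop_soret("fraction %.3g never reached within the series (final fraction attained: %.4g)",
               fraction, rr[length(rr)])
  }
  k <- hit[1]
  if (k == 1) return(tt[1])
  # linear interpolation between the bracketing snapshots
  t_lo <- tt[k - 1]; t_hi <- tt[k]
  f_lo <- rr[k - 1]; f_hi <- rr[k]
  t_lo + (fraction - f_lo) / (f_hi - f_lo) * (t_hi - t_lo)
}
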