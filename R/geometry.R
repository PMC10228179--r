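# Domain description: capillary geometry, laser source, medium, and the
# axisymmetric (r, z) finite-volume grid shared by the heat and mass solvers.

#' Capillary sample geometry
#'
#' Axisymmetric computational domain for the heated capillary: radial
#' coordinate r in \[0, capillary_radius\], axial coordinate z in
#' \[-axial_half_length, +axial_half_length\] with z = 0 at the laser focal
#' plane and the beam travelling along z.
#'
#' @param capillary_radius Capillary inner radius, m. Default 2e-4 (0.2 mm).
#' @param axial_half_length Half-length of the modelled axial extent, m.
#' @return An object of class `capillary_geometry`.
#' @export
#' @examples
#' capillary_geometry()
capillary_geometry <- function(capillary_radius = 2e-4, axial_half_length = 2e-4) {
  check_that(is.numeric(capillary_radius) && length(capillary_radius) == 1 &&
               capillary_radius > 0, "capillary_radius must be a positive length (m)")
  check_that(is.numeric(axial_half_length) && length(axial_half_length) == 1 &&
               axial_half_length > 0, "axial_half_length must be a positive length (m)")
  structure(
    list(capillary_radius = capillary_radius,
         axial_half_length = axial_half_length),
    class = "capillary_geometry"
  )
}

#' Infrared heating laser description
#'
#' Parameters of the IR laser heat load: a Gaussian transverse profile with
#' Beer-Lambert attenuation along the propagation axis. The beam diameter is
#' interpreted as the 1/e^2 intensity diameter, so the Gaussian widths are
#' `sigma_x = sigma_y = beam_diameter / 4`; both can be overridden.
#'
#' @param power_Q0 Laser input power, W.
#' @param reflection_Rc Reflection coefficient of the capillary wall (0-1).
#' @param absorption_Ac Absorption coefficient of the sample, 1/m
#'   (default 50/m = 0.50 1/cm).
#' @param beam_diameter 1/e^2 beam diameter at the waist, m.
#' @param focus_r0,focus_z0 Focal-point coordinates, m (on-axis by default).
#' @param sigma_x,sigma_y Gaussian widths, m; derived from `beam_diameter`
#'   when `NULL`.
#' @return An object of class `laser_source`.
#' @export
#' @examples
#' laser_source()          # instrument defaults: 0.05 W, 10 um beam
laser_source <- function(power_Q0 = 0.05, reflection_Rc = 0.05,
                         absorption_Ac = 50, beam_diameter = 1e-5,
                         focus_r0 = 0, focus_z0 = 0,
                         sigma_x = NULL, sigma_y = NULL) {
  check_that(power_Q0 >= 0, "power_Q0 must be >= 0 (W)")
  check_that(reflection_Rc >= 0 && reflection_Rc < 1,
             "reflection_Rc must be in [0, 1)")
  check_that(absorption_Ac >= 0, "absorption_Ac must be >= 0 (1/m)")
  check_that(beam_diameter > 0, "beam_diameter must be > 0 (m)")
  if (is.null(sigma_x)) sigma_x <- beam_diameter / 4
  if (is.null(sigma_y)) sigma_y <- beam_diameter / 4
  check_that(sigma_x > 0 && sigma_y > 0, "sigma_x and sigma_y must be > 0")
  structure(
    list(power_Q0 = power_Q0, reflection_Rc = reflection_Rc,
         absorption_Ac = absorption_Ac, beam_diameter = beam_diameter,
         focus_r0 = focus_r0, focus_z0 = focus_z0,
         sigma_x = sigma_x, sigma_y = sigma_y),
    class = "laser_source"
  )
}

#' Thermal properties of the sample medium
#'
#' Defaults are liquid water at room temperature.
#'
#' @param thermal_conductivity W/(m K).
#' @param density kg/m^3.
#' @param heat_capacity J/(kg K).
#' @param ambient_temperature Ambient (wall/boundary) temperature, K. The
#'   absolute level is configurable; only temperature rises are physically
#'   constrained by the model.
#' @return An object of class `medium`.
#' @export
medium_water <- function(thermal_conductivity = 0.6, density = 998,
                         heat_capacity = 4182, ambient_temperature = 293.15) {
  check_that(thermal_conductivity > 0, "thermal_conductivity must be > 0")
  check_that(density > 0, "density must be > 0")
  check_that(heat_capacity > 0, "heat_capacity must be > 0")
  check_that(ambient_temperature > 0, "ambient_temperature must be > 0 (K)")
  structure(
    list(thermal_conductivity = thermal_conductivity, density = density,
         heat_capacity = heat_capacity,
         ambient_temperature = ambient_temperature),
    class = "medium"
  )
}

#' Build an axisymmetric finite-volume grid
#'
#' Node-centred grid on (r, z) with the first radial node on the axis (r = 0).
#' Cell faces sit midway between nodes; the cell volume is the axisymmetric
#' annulus pi (rf_out^2 - rf_in^2) dz. The default radial spacing is graded:
#' fine (`dr_fine`) across the beam waist, intermediate out to `r_mid`, then
#' geometric coarsening to the capillary wall. Axial spacing is uniform.
#'
#' @param geom A [capillary_geometry()].
#' @param dr_fine Radial spacing inside the fine region, m.
#' @param r_fine Outer radius of the fine region, m.
#' @param dr_mid Radial spacing between `r_fine` and `r_mid`, m.
#' @param r_mid Outer radius of the intermediate region, m.
#' @param n_outer Number of geometric nodes from `r_mid` to the wall.
#' @param dz Axial spacing, m.
#' @param refine Refinement factor; 2 halves all spacings (used for mesh
#'   convergence checks).
#' @return An object of class `fv_grid` with nodes, faces, volumes and the
#'   precomputed face connectivity used by both solvers.
#' @export
#' @examples
#' g <- make_grid(capillary_geometry())
#' g$nr * g$nz          # total number of nodes
make_grid <- function(geom = capillary_geometry(),
                      dr_fine = 5e-7, r_fine = 5e-6,
                      dr_mid = 1.5e-6, r_mid = 2e-5,
                      n_outer = 10, dz = 1e-5, refine = 1) {
  check_that(inherits(geom, "capillary_geometry"), "geom must be a capillary_geometry")
  check_that(refine >= 1, "refine must be >= 1")
  R <- geom$capillary_radius
  L <- geom$axial_half_length
  check_that(r_mid < R, "r_mid must lie inside the capillary radius")
  r1 <- seq(0, r_fine, by = dr_fine / refine)
  r2 <- seq(r_fine, r_mid, by = dr_mid / refine)[-1]
  n3 <- ceiling(n_outer * refine) + 1
  r3 <- exp(seq(log(r_mid), log(R), length.out = n3))[-1]
  r <- c(r1, r2, r3)
  r[length(r)] <- R
  nzh <- ceiling(L / (dz / refine))
  z <- seq(-L, L, length.out = 2 * nzh + 1)
  grid_from_nodes(r, z, geom)
}

#' Build a grid from explicit node coordinate vectors
#'
#' @param r Strictly increasing radial node coordinates, m; first must be 0.
#' @param z Strictly increasing axial node coordinates, m.
#' @param geom The [capillary_geometry()] the grid covers.
#' @return An `fv_grid` object.
#' @export
grid_from_nodes <- function(r, z, geom = capillary_geometry()) {
  check_that(all(diff(r) > 0) && all(diff(z) > 0),
             "node coordinates must be strictly increasing")
  check_that(abs(r[1]) < 1e-15, "first radial node must lie on the axis (r = 0)")
  nr <- length(r); nz <- length(z)
  rf <- c(0, (r[-1] + r[-nr]) / 2, r[nr])       # radial faces, length nr + 1
  zf <- c(z[1], (z[-1] + z[-nz]) / 2, z[nz])    # axial faces, length nz + 1
  a_r <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2)      # annular cross-section area
  dzc <- diff(zf)                               # cell heights
  vol <- outer(a_r, dzc)                        # cell volumes, nr x nz

  idx <- function(i, j) i + (j - 1L) * nr
  # Radial faces between (i, j) and (i+1, j): area 2 pi r_face dz, span dr.
  i_r <- rep(seq_len(nr - 1), times = nz)
  j_r <- rep(seq_len(nz), each = nr - 1)
  rad_from <- idx(i_r, j_r)
  rad_to   <- idx(i_r + 1L, j_r)
  rad_Ah   <- (2 * pi * rf[i_r + 1L] * dzc[j_r]) / (r[i_r + 1L] - r[i_r])
  # Axial faces between (i, j) and (i, j+1): area = annular area, span dz.
  i_z <- rep(seq_len(nr), times = nz - 1)
  j_z <- rep(seq_len(nz - 1), each = nr)
  ax_from <- idx(i_z, j_z)
  ax_to   <- idx(i_z, j_z + 1L)
  ax_Ah   <- a_r[i_z] / (z[j_z + 1L] - z[j_z])

  boundary <- matrix(FALSE, nr, nz)
  boundary[nr, ] <- TRUE          # capillary wall
  boundary[, 1] <- TRUE           # z = -L
  boundary[, nz] <- TRUE          # z = +L

  structure(
    list(r = r, z = z, nr = nr, nz = nz, rf = rf, zf = zf,
         a_r = a_r, dzc = dzc, vol = vol,
         face_from = c(rad_from, ax_from),
         face_to = c(rad_to, ax_to),
         face_Ah = c(rad_Ah, ax_Ah),
         boundary = boundary,
         geom = geom),
    class = "fv_grid"
  )
}

#' @export
print.fv_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric finite-volume grid: %d (r) x %d (z) = %d nodes\n",
              x$nr, x$nz, x$nr * x$nz))
  cat(sprintf("  r: 0 .. %.3g m (min spacing %.3g m)\n", max(x$r), min(diff(x$r))))
  cat(sprintf("  z: %.3g .. %.3g m (spacing %.3g m)\n", min(x$z), max(x$z),
              x$z[2] - x$z[1]))
  invisible(x)
}

# Index of the node nearest to (r0, z0).
focus_index <- function(grid, r0 = 0, z0 = 0) {
  i <- which.min(abs(grid$r - r0))
  j <- which.min(abs(grid$z - z0))
  c(i = i, j = j)
}
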