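# Laser heat-load field and conduction solvers.

test_that("heat source obeys energy bookkeeping and the Gaussian profile", {
  g <- fx_grid(); geom <- fx_geom()
  q <- fx_source()
  # closed-form absorbed power: Q0 (1-Rc) (1-exp(-Ac * 2L))
  expected <- 0.05 * 0.95 * (1 - exp(-50 * 4e-4))
  expect_equal(expected, 9.405e-4, tolerance = 1e-3)
  expect_equal(attr(q, "absorbed_power"), expected, tolerance = 1e-12)
  # discrete volume integral (quadrature) matches the bookkeeping
  expect_equal(sum(q * g$vol), expected, tolerance = 1e-10)
  # Gaussian transverse decay: value at r = 5 sigma below e^-12.5 of on-axis
  sigma <- fx_laser()$sigma_x
  i5 <- which.min(abs(g$r - 5 * sigma))
  jmid <- which.min(abs(g$z))
  expect_lt(q[i5, jmid], exp(-12.5) * q[1, jmid] * 1.01)
})

test_that("zero laser power produces an identically zero source", {
  q0 <- heat_source_field(laser_source(power_Q0 = 0), fx_geom(), fx_grid())
  expect_true(all(q0 == 0))
  expect_equal(attr(q0, "absorbed_power"), 0)
})

test_that("a grid that cannot resolve the beam waist is refused", {
  g_coarse <- grid_from_nodes(c(0, 5e-5, 1e-4, 1.5e-4, 2e-4),
                              seq(-2e-4, 2e-4, length.out = 11), fx_geom())
  expect_error(heat_source_field(fx_laser(), fx_geom(), g_coarse),
               "beam waist")
})

test_that("steady solve: zero source stays at ambient; defaults heat the focus by 2-8 K", {
  g <- fx_grid(); med <- fx_medium()
  T0 <- solve_steady_temperature(med, matrix(0, g$nr, g$nz), fx_geom(), g)
  expect_equal(max(abs(T0 - med$ambient_temperature)), 0, tolerance = 1e-10)

  Ts <- fx_steady()
  rise <- max(Ts) - med$ambient_temperature
  expect_gt(rise, 2)   # consistent with a focal temperature near 298 K
  expect_lt(rise, 8)
  # maximum principle: no temperature below ambient, peak on the axis
  expect_gte(min(Ts), med$ambient_temperature - 1e-9)
  expect_equal(unname(which(Ts == max(Ts), arr.ind = TRUE)[1, "row"]), 1L)
})

test_that("steady-state boundary outflow balances the volume-integrated source", {
  g <- fx_grid(); med <- fx_medium()
  Ts <- fx_steady()
  Tv <- as.vector(Ts)
  gcond <- med$thermal_conductivity * g$face_Ah
  flux <- gcond * (Tv[g$face_from] - Tv[g$face_to])   # from -> to, W
  bnd <- as.vector(g$boundary)
  outflow <- sum(flux[bnd[g$face_to] & !bnd[g$face_from]]) -
    sum(flux[bnd[g$face_from] & !bnd[g$face_to]])
  source_interior <- sum((fx_source() * g$vol)[!g$boundary])
  expect_equal(outflow, source_interior, tolerance = 0.01)
})

test_that("transient solve starts at ambient, reaches steady state, and relaxes after off", {
  med <- fx_medium()
  ser <- fx_establishment_series()
  expect_equal(max(abs(ser$fields[, , 1] - med$ambient_temperature)), 0)
  fi <- ser$focus
  focal <- ser$fields[fi["i"], fi["j"], ]
  # monotone non-decreasing focal temperature while the laser is on
  expect_true(all(diff(focal) > -1e-9))
  # within 0.5% of the steady rise well before 2 s
  steady_rise <- ser$steady[fi["i"], fi["j"]] - med$ambient_temperature
  expect_equal(focal[length(focal)] - med$ambient_temperature, steady_rise,
               tolerance = 5e-3)
  # laser never on: field stays at ambient
  quiet <- solve_transient_temperature(med, fx_source(), fx_geom(), fx_grid(),
                                       times = seq(0, 0.5, 0.05),
                                       laser_on = 100, laser_off = 200)
  expect_equal(max(abs(quiet$fields - med$ambient_temperature)), 0)
  # off-phase relaxation back toward ambient
  cycle <- solve_transient_temperature(med, fx_source(), fx_geom(), fx_grid(),
                                       times = c(0, 1, 1.5, 3),
                                       laser_on = 0, laser_off = 1.5)
  f_end <- cycle$fields[fi["i"], fi["j"], 4] - med$ambient_temperature
  f_on <- cycle$fields[fi["i"], fi["j"], 2] - med$ambient_temperature
  expect_lt(f_end, 0.05 * f_on)
})

test_that("the temperature gradient establishes within 1 s of laser-on", {
  ser <- fx_establishment_series()
  t99 <- gradient_establishment_time(ser, 0.99)
  expect_lte(t99, 1)
  expect_gt(t99, 0)
  # establishment time is monotone in the threshold fraction, zero at zero
  expect_equal(gradient_establishment_time(ser, 0), 0)
  fr <- c(0.5, 0.9, 0.99)
  tt <- vapply(fr, function(f) gradient_establishment_time(ser, f), 0)
  expect_true(all(diff(tt) >= 0))
  # a fraction never reached is reported, not silently clamped
  short <- solve_transient_temperature(fx_medium(), fx_source(), fx_geom(),
                                       fx_grid(), times = seq(0, 0.02, 0.01),
                                       laser_on = 0, laser_off = 20)
  expect_error(gradient_establishment_time(short, 0.999), "never reached")
})

test_that("peak rise and establishment time are mesh-converged (< 2% under 2x refinement)", {
  med <- fx_medium(); geom <- fx_geom()
  g2 <- make_grid(geom, refine = 2)
  q2 <- heat_source_field(fx_laser(), geom, g2)
  Ts2 <- solve_steady_temperature(med, q2, geom, g2)
  rise1 <- max(fx_steady()) - med$ambient_temperature
  rise2 <- max(Ts2) - med$ambient_temperature
  expect_equal(rise1, rise2, tolerance = 0.02)
  ser2 <- solve_transient_temperature(med, q2, geom, g2,
                                      times = seq(0, 1.5, 0.01),
                                      laser_on = 0, laser_off = 20)
  t99_1 <- gradient_establishment_time(fx_establishment_series(), 0.99)
  t99_2 <- gradient_establishment_time(ser2, 0.99)
  expect_equal(t99_1, t99_2, tolerance = 0.02)
})
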