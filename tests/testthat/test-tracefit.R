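# Two-stage deconvolution: fluorophore decay fit, particle-trace fit, and
# replicate aggregation.

test_that("stage 1 recovers the decay constant exactly from a noiseless trace", {
  tr <- generate_fluorophore_trace(trace_recipe("fluorophore", decay_rate_k = -0.22))
  fit <- fit_fluorophore(tr)
  expect_equal(fit$decay_rate_k, -0.22, tolerance = 1e-6)
  expect_equal(fit$background_B, 200, tolerance = 1e-6)
  expect_equal(fit$amplitude_C, 800, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_length(fit$flags, 0)
})

test_that("a constant trace yields the degenerate fit with k flagged unidentifiable", {
  tr <- generate_fluorophore_trace(trace_recipe("fluorophore", amplitude = 0,
                                                background = 500))
  fit <- fit_fluorophore(tr)
  expect_equal(fit$amplitude_C, 0)
  expect_equal(fit$background_B, 500)
  expect_true(is.na(fit$decay_rate_k))
  expect_true("k-unidentifiable" %in% fit$flags)
})

test_that("stage 1 is accurate under noise: median |k error| < 0.01 over 100 seeds", {
  errs <- vapply(1:100, function(seed) {
    tr <- generate_fluorophore_trace(
      trace_recipe("fluorophore", decay_rate_k = -0.22, noise_sigma = 0.01,
                   seed = seed))
    abs(fit_fluorophore(tr)$decay_rate_k + 0.22)
  }, 0)
  expect_lt(stats::median(errs), 0.01)
})

test_that("the closed-form linear subproblem matches an lm() oracle to 1e-10 relative", {
  lib <- fx_library()
  tr <- fx_particle_trace(0.66, seed = 3, noise = 0.02)
  fit <- fit_particle_trace(tr, -0.22, lib)
  sel <- tr$times >= tr$laser_on & tr$times <= tr$laser_off
  t <- tr$times[sel] - tr$laser_on
  y <- tr$intensities[sel]
  conc <- stats::approx(lib$times,
                        interpolate_conc_curve(lib, fit$soret_ST)$values, t)$y
  ref <- stats::lm(y ~ I(exp(-0.22 * t) * conc))
  expect_equal(fit$background_d0, unname(stats::coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$amplitude_e0, unname(stats::coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$sse, sum(stats::residuals(ref)^2), tolerance = 1e-10)
})

test_that("noiseless particle traces round-trip S_T through the two-stage fit", {
  lib <- fx_library()
  # the printed worked-example value plus off-grid truths across the range
  for (truth in c(0.07, -1.31, 0.33, 1.91, -0.04)) {
    tr <- fx_particle_trace(truth)
    fit <- fit_particle_trace(tr, -0.22, lib)
    expect_lt(abs(fit$soret_ST - truth), max(0.02, 0.05 * abs(truth)))
    expect_equal(fit$background_d0, 200, tolerance = 1e-4)
    expect_equal(fit$amplitude_e0, 800, tolerance = 1e-4)
  }
})

test_that("parabolic refinement agrees with brute force on a 10x finer grid", {
  lib <- fx_library()
  tr <- fx_particle_trace(0.62, seed = 5, noise = 1e-4)
  fit <- fit_particle_trace(tr, -0.22, lib)
  sel <- tr$times >= tr$laser_on & tr$times <= tr$laser_off
  t <- tr$times[sel] - tr$laser_on
  y <- tr$intensities[sel]
  decay <- exp(-0.22 * t)
  brute <- seq(0.25, 1, by = 0.0025)   # 10x finer than the refinement step
  sse <- vapply(brute, function(s) {
    conc <- stats::approx(lib$times, interpolate_conc_curve(lib, s)$values, t)$y
    m <- decay * conc
    sum(stats::lm.fit(cbind(1, m), y)$residuals^2)
  }, 0)
  expect_lt(abs(fit$soret_ST - brute[which.min(sse)]), 0.005)
})

test_that("a trace without thermophoresis fits S_T ~ 0 and is flagged weakly identified", {
  tr <- generate_fluorophore_trace(trace_recipe("fluorophore", decay_rate_k = -0.22))
  tr$role <- "particle"
  fit <- fit_particle_trace(tr, -0.22, fx_library())
  expect_lt(abs(fit$soret_ST), 0.02)
  expect_true("weakly-identified" %in% fit$flags)
})

test_that("an SSE minimum on the library boundary is flagged range-limited", {
  fit <- fit_particle_trace(fx_particle_trace(2.5), -0.22, fx_library())
  expect_true("range-limited" %in% fit$flags)
  expect_equal(fit$soret_ST, 2.5, tolerance = 0.05)
})

test_that("extract_soret aggregates replicates with n-1 SD and reports n", {
  lib <- fx_library()
  ff <- generate_replicate_set(trace_recipe("fluorophore", decay_rate_k = -0.22),
                               n = 2, base_seed = 1)
  ps <- generate_replicate_set(trace_recipe("particle", soret_ST = 0.05,
                                            decay_rate_k = -0.22),
                               n = 8, base_seed = 10, library = lib)
  res <- extract_soret(ff, ps, lib)
  expect_equal(res$n, 8L)
  expect_equal(res$mean_ST, 0.05, tolerance = 1e-4)
  expect_equal(res$sd_ST, 0, tolerance = 1e-6)   # noiseless replicates agree
  expect_equal(res$decay_rate_k, -0.22, tolerance = 1e-6)
  rep <- soret_report(list(`20 nm` = res), literature_ST = c(`20 nm` = 0.05))
  expect_equal(rep$condition, "20 nm")
  expect_equal(rep$literature_ST_per_K, 0.05)
  expect_equal(rep$mean_ST_per_K, 0.05, tolerance = 1e-4)
})

test_that("replicate SD grows with injected noise amplitude", {
  lib <- fx_library()
  sd_at <- function(noise) {
    ps <- generate_replicate_set(
      trace_recipe("particle", soret_ST = 0.66, decay_rate_k = -0.22,
                   noise_sigma = noise),
      n = 8, base_seed = 100, library = lib)
    fits <- lapply(ps, fit_particle_trace, decay_rate_k = -0.22, library = lib)
    stats::sd(vapply(fits, function(f) f$soret_ST, 0))
  }
  s_small <- sd_at(1e-4)
  s_large <- sd_at(1e-3)
  expect_gt(s_small, 0)
  expect_gt(s_large, 2 * s_small)   # ~linear scaling in the linear regime
})

test_that("QC flags injected aggregation spikes and passes smooth traces", {
  smooth <- generate_fluorophore_trace(
    trace_recipe("fluorophore", decay_rate_k = -0.22, noise_sigma = 0.005,
                 seed = 42))
  qc0 <- qc_bumpiness(smooth)
  expect_equal(qc0$spike_count, 0L)
  expect_equal(qc0$verdict, "pass")
  sigma <- 0.005 * 800
  spiked <- inject_aggregation_spikes(smooth, c(8, 14, 21), 10 * sigma)
  qc3 <- qc_bumpiness(spiked)
  expect_equal(qc3$spike_count, 3L)
  expect_equal(qc3$verdict, "flag")
  expect_equal(sort(qc3$spike_times), c(8, 14, 21), tolerance = 0.1)
  # infinite threshold always passes
  expect_equal(qc_bumpiness(spiked, threshold = Inf)$verdict, "pass")
  # noiseless smooth trace (with its laser-on/off kinks) also passes
  clean <- generate_fluorophore_trace(trace_recipe("fluorophore", decay_rate_k = -0.22))
  expect_equal(qc_bumpiness(clean)$spike_count, 0L)
  short <- mst_trace(seq(0, 2, length.out = 21), rep(1, 21), 0, 2,
                     role = "fluorophore")
  expect_error(qc_bumpiness(short), "too short")
})

test_that("role preconditions are enforced on both fit stages", {
  ff <- generate_fluorophore_trace(trace_recipe("fluorophore"))
  expect_error(fit_particle_trace(ff, -0.22, fx_library()), "particle")
  ps <- fx_particle_trace(0.05)
  expect_error(fit_fluorophore(ps), "fluorophore")
})
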