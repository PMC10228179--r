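# Synthetic trace generator: forward-model fidelity, seeding, QC fixtures.

test_that("noiseless fluorophore traces match the closed-form decay exactly", {
  tr <- generate_fluorophore_trace(trace_recipe("fluorophore", decay_rate_k = -0.22))
  sel <- tr$times >= tr$laser_on & tr$times <= tr$laser_off
  t <- tr$times[sel] - tr$laser_on
  expect_equal(tr$intensities[sel], 200 + 800 * exp(-0.22 * t), tolerance = 1e-15)
  # flat pre-laser baseline at background + amplitude
  expect_true(all(tr$intensities[tr$times < tr$laser_on] == 1000))
  # constant trace when the amplitude is zero
  flat <- generate_fluorophore_trace(trace_recipe("fluorophore", amplitude = 0))
  expect_true(all(flat$intensities == 200))
})

test_that("the same recipe and seed reproduce a trace bit-identically", {
  r <- trace_recipe("fluorophore", noise_sigma = 0.02, seed = 123)
  expect_identical(generate_fluorophore_trace(r)$intensities,
                   generate_fluorophore_trace(r)$intensities)
  r2 <- r; r2$seed <- 124L
  expect_false(identical(generate_fluorophore_trace(r)$intensities,
                         generate_fluorophore_trace(r2)$intensities))
})

test_that("a particle trace at S_T = 0 equals the fluorophore trace with the same parameters", {
  pr <- trace_recipe("particle", soret_ST = 0, decay_rate_k = -0.22, seed = 9)
  fr <- trace_recipe("fluorophore", decay_rate_k = -0.22, seed = 9)
  pt <- generate_particle_trace(pr, fx_library())
  ft <- generate_fluorophore_trace(fr)
  expect_equal(pt$intensities, ft$intensities, tolerance = 1e-9)
})

test_that("depletion depth of generated particle traces increases with S_T", {
  depth_at <- function(s) {
    tr <- fx_particle_trace(s)
    sel <- tr$times >= tr$laser_on & tr$times <= tr$laser_off
    t <- tr$times[sel] - tr$laser_on
    # remove the fluorophore decay factor to isolate Conc(t)
    conc <- (tr$intensities[sel] - 200) / (800 * exp(-0.22 * t))
    1 - min(conc)
  }
  depths <- vapply(c(0.25, 0.75, 1.5, 2.25), depth_at, 0)
  expect_true(all(diff(depths) > 0))
})

test_that("S_T outside the library range is refused at generation time", {
  r <- trace_recipe("particle", soret_ST = 3, decay_rate_k = -0.22)
  expect_error(generate_particle_trace(r, fx_library()), "outside the library range")
})

test_that("invalid recipes are refused with the violated fields listed", {
  expect_error(trace_recipe("fluorophore", n_points = 5),
               "n_points")
  expect_error(trace_recipe("fluorophore", noise_sigma = -0.1, laser_on = 10,
                            laser_off = 2),
               "noise_sigma.*laser_on")
  expect_error(trace_recipe("particle"), "soret_ST")
})

test_that("replicate sets share the truth and differ only by noise", {
  r <- trace_recipe("fluorophore", noise_sigma = 0, seed = 50)
  set0 <- generate_replicate_set(r, n = 8)
  expect_length(set0, 8)
  for (tr in set0[-1]) expect_equal(tr$intensities, set0[[1]]$intensities)
  rn <- trace_recipe("fluorophore", noise_sigma = 0.01, seed = 50)
  setn <- generate_replicate_set(rn, n = 8)
  for (i in 2:8) {
    expect_false(identical(setn[[i]]$intensities, setn[[1]]$intensities))
  }
  res <- extract_soret(set0[1],
                       generate_replicate_set(
                         trace_recipe("particle", soret_ST = 0.18,
                                      decay_rate_k = -0.22),
                         n = 8, library = fx_library()),
                       fx_library())
  expect_equal(res$n, 8L)
})

test_that("spike injection is additive, reversible in spirit, and validated", {
  tr <- generate_fluorophore_trace(trace_recipe("fluorophore", noise_sigma = 0.01))
  expect_identical(inject_aggregation_spikes(tr, numeric(0), 10), tr)
  zero <- inject_aggregation_spikes(tr, c(10, 12), 0)
  expect_equal(zero$intensities, tr$intensities, tolerance = 1e-12)
  expect_error(inject_aggregation_spikes(tr, 99, 10), "outside the trace span")
  bumped <- inject_aggregation_spikes(tr, 10, 50)
  i <- which.min(abs(tr$times - 10))
  expect_equal(bumped$intensities[i] - tr$intensities[i], 50)
  expect_equal(bumped$intensities[-i], tr$intensities[-i])
})
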