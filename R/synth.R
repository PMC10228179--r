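# Seeded synthetic MST trace generator. Emulates the canonical trace
# morphology: a flat pre-laser baseline, an exponential-times-depletion decay
# while the IR laser is on, and a plateau after switch-off (the recovery
# phase is not modelled quantitatively; the fit only uses the on-phase).

#' Recipe for a synthetic MST trace
#'
#' @param role `"fluorophore"` or `"particle"`.
#' @param background Background intensity, counts (B for fluorophore traces,
#'   d0 for particle traces).
#' @param amplitude Initial decaying intensity, counts (C, resp. e0).
#' @param decay_rate_k Signed exponent coefficient of the fluorophore decay,
#'   1/s (negative decays; e.g. -0.22).
#' @param soret_ST Ground-truth Soret coefficient, 1/K (particle traces only).
#' @param noise_sigma Additive Gaussian noise SD as a fraction of `amplitude`.
#' @param n_points Number of samples (>= 20).
#' @param duration Trace duration, s.
#' @param laser_on,laser_off Laser switching times, s.
#' @param seed Integer seed; the same recipe and seed reproduce the trace
#'   bit-identically.
#' @return Object of class `trace_recipe`.
#' @export
#' @examples
#' trace_recipe("fluorophore", decay_rate_k = -0.22, seed = 1)
trace_recipe <- function(role = c("fluorophore", "particle"),
                         background = 200, amplitude = 800,
                         decay_rate_k = -0.22, soret_ST = NULL,
                         noise_sigma = 0, n_points = 601, duration = 30,
                         laser_on = 5, laser_off = 25, seed = 1) {
  role <- match.arg(role)
  bad <- character()
  if (!(is.numeric(n_points) && n_points >= 20)) bad <- c(bad, "n_points (must be >= 20)")
  if (!(is.numeric(noise_sigma) && noise_sigma >= 0)) bad <- c(bad, "noise_sigma (must be >= 0)")
  if (!(is.numeric(duration) && duration > 0)) bad <- c(bad, "duration (must be > 0)")
  if (!(is.numeric(laser_on) && is.numeric(laser_off) && laser_on < laser_off))
    bad <- c(bad, "laser_on/laser_off (need laser_on < laser_off)")
  if (!(is.numeric(background))) bad <- c(bad, "background")
  if (!(is.numeric(amplitude))) bad <- c(bad, "amplitude")
  if (!(is.numeric(decay_rate_k) && is.finite(decay_rate_k))) bad <- c(bad, "decay_rate_k")
  if (role == "particle" && is.null(soret_ST)) bad <- c(bad, "soret_ST (required for particle traces)")
  if (!(is.numeric(seed) && length(seed) == 1)) bad <- c(bad, "seed")
  if (length(bad)) {
    stop_soret("invalid trace recipe; violated fields: %s", paste(bad, collapse = ", "))
  }
  structure(
    list(role = role, background = background, amplitude = amplitude,
         decay_rate_k = decay_rate_k, soret_ST = soret_ST,
         noise_sigma = noise_sigma, n_points = as.integer(n_points),
         duration = duration, laser_on = laser_on, laser_off = laser_off,
         seed = as.integer(seed)),
    class = "trace_recipe"
  )
}

# Shared assembly: piecewise trace from an on-segment model function.
assemble_trace <- function(recipe, on_model, trace_id, metadata) {
  times <- seq(0, recipe$duration, length.out = recipe$n_points)
  pre <- times < recipe$laser_on
  on <- times >= recipe$laser_on & times <= recipe$laser_off
  post <- times > recipe$laser_off
  y <- numeric(length(times))
  y[pre] <- recipe$background + recipe$amplitude
  y[on] <- on_model(times[on] - recipe$laser_on)
  last_on <- recipe$laser_off - recipe$laser_on
  y[post] <- on_model(last_on)   # plateau after switch-off
  if (recipe$noise_sigma > 0) {
    y <- y + with_seed(recipe$seed,
                       stats::rnorm(length(y),
                                    sd = recipe$noise_sigma * abs(recipe$amplitude)))
  }
  mst_trace(times, y, recipe$laser_on, recipe$laser_off,
            trace_id = trace_id, role = recipe$role, metadata = metadata)
}

#' Generate a synthetic free-fluorophore trace
#'
#' Forward model of the stage-1 decay: baseline at `background + amplitude`
#' before laser-on, `B + C exp(k t)` during the on-phase (t re-zeroed at
#' laser-on), plateau after switch-off, plus seeded additive Gaussian noise.
#'
#' @param recipe A [trace_recipe()] with role `"fluorophore"`.
#' @return An [mst_trace()]; the generator ground truth is stored in
#'   `metadata$truth`.
#' @export
generate_fluorophore_trace <- function(recipe) {
  check_that(inherits(recipe, "trace_recipe"), "recipe must be a trace_recipe")
  check_that(recipe$role == "fluorophore",
             "recipe role must be 'fluorophore' (got '%s')", recipe$role)
  assemble_trace(
    recipe,
    function(t) recipe$background + recipe$amplitude * exp(recipe$decay_rate_k * t),
    trace_id = sprintf("ff-seed%d", recipe$seed),
    metadata = list(truth = list(background_B = recipe$background,
                                 amplitude_C = recipe$amplitude,
                                 decay_rate_k = recipe$decay_rate_k))
  )
}

#' Generate a synthetic particle trace
#'
#' Forward model of the stage-2 trace: `d0 + e0 exp(k t) Conc_ST(t)` during
#' the on-phase, with Conc(t) taken from the library by monotone
#' interpolation at the ground-truth `soret_ST`.
#'
#' @param recipe A [trace_recipe()] with role `"particle"` and `soret_ST`
#'   inside the library range.
#' @param library A `conc_library`.
#' @return An [mst_trace()] with ground truth in `metadata$truth`.
#' @export
generate_particle_trace <- function(recipe, library) {
  check_that(inherits(recipe, "trace_recipe"), "recipe must be a trace_recipe")
  check_that(recipe$role == "particle",
             "recipe role must be 'particle' (got '%s')", recipe$role)
  curve <- interpolate_conc_curve(library, recipe$soret_ST)
  assemble_trace(
    recipe,
    function(t) recipe$background + recipe$amplitude *
      exp(recipe$decay_rate_k * t) *
      resample_curve(curve$times, curve$values, t),
    trace_id = sprintf("ps-seed%d", recipe$seed),
    metadata = list(truth = list(background_d0 = recipe$background,
                                 amplitude_e0 = recipe$amplitude,
                                 decay_rate_k = recipe$decay_rate_k,
                                 soret_ST = recipe$soret_ST))
  )
}

#' Generate a replicate set of synthetic traces
#'
#' `n` traces sharing the recipe's ground truth with independent noise:
#' seeds run `base_seed, base_seed + 1, ..., base_seed + n - 1`.
#'
#' @param recipe A [trace_recipe()].
#' @param n Number of replicates (>= 1).
#' @param base_seed First seed.
#' @param library A `conc_library` (required for particle recipes).
#' @return List of [mst_trace()] objects.
#' @export
generate_replicate_set <- function(recipe, n = 8, base_seed = recipe$seed,
                                   library = NULL) {
  check_that(n >= 1, "n must be >= 1")
  lapply(seq_len(n) - 1L, function(i) {
    r <- recipe
    r$seed <- as.integer(base_seed + i)
    if (r$role == "particle") {
      check_that(!is.null(library), "a conc_library is required for particle recipes")
      tr <- generate_particle_trace(r, library)
    } else {
      tr <- generate_fluorophore_trace(r)
    }
    tr$trace_id <- sprintf("%s-rep%d", tr$trace_id, i + 1L)
    tr
  })
}

#' Inject aggregation-like spikes into a trace
#'
#' Adds transient single-sample jumps at the given times, emulating an
#' aggregate passing through the detection region. The input trace is not
#' modified; a new trace is returned.
#'
#' @param trace An [mst_trace()].
#' @param spike_times Times of the jumps, s; must lie within the trace span.
#' @param magnitude Jump height, counts (recycled over spikes).
#' @return A new [mst_trace()].
#' @export
inject_aggregation_spikes <- function(trace, spike_times, magnitude) {
  check_that(inherits(trace, "mst_trace"), "trace must be an mst_trace")
  if (!length(spike_times)) return(trace)
  rng <- range(trace$times)
  bad <- spike_times < rng[1] | spike_times > rng[2]
  if (any(bad)) {
    stop_soret("spike time(s) outside the trace span [%.4g, %.4g] s: %s",
               rng[1], rng[2], paste(signif(spike_times[bad], 4), collapse = ", "))
  }
  magnitude <- rep_len(magnitude, length(spike_times))
  out <- trace
  for (k in seq_along(spike_times)) {
    i <- which.min(abs(trace$times - spike_times[k]))
    out$intensities[i] <- out$intensities[i] + magnitude[k]
  }
  out
}
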