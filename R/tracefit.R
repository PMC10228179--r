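# Two-stage deconvolution of MST traces.
# Stage 1 fits the free-fluorophore intensity decay (TRIC + photobleaching,
# lumped into one exponential): intensity = B + C exp(k t).
# Stage 2 fixes that decay rate and fits the particle trace
#   intensity = d0 + e0 exp(k t) Conc_ST(t)
# by closed-form linear least squares in (d0, e0) at each library S_T,
# taking the SSE-minimizing S_T with local grid refinement.
#
# Symbol mapping to the usual trace-model notation: background_B/amplitude_C
# are the fluorophore background and initial intensity, decay_rate_k is the
# signed exponent coefficient (negative = decay; the conventionally printed
# "decay constant" c, e.g. -0.22 1/s), and background_d0/amplitude_e0 are the
# particle-trace background and initial intensity (renamed from D and E so
# that D can keep denoting the diffusion coefficient).

#' Construct an MST trace
#'
#' @param times Sample times, s; strictly increasing.
#' @param intensities Fluorescence intensities, counts (arbitrary units).
#' @param laser_on,laser_off Laser switching times, s.
#' @param trace_id Identifier string.
#' @param role `"fluorophore"` (free dye) or `"particle"`.
#' @param metadata Named list of free-form metadata (buffer, particle size,
#'   excitation settings, generator ground truth, ...).
#' @return Object of class `mst_trace`.
#' @export
mst_trace <- function(times, intensities, laser_on, laser_off,
                      trace_id = "trace", role = c("particle", "fluorophore"),
                      metadata = list()) {
  role <- match.arg(role)
  check_that(length(times) == length(intensities),
             "times and intensities differ in length")
  check_that(all(diff(times) > 0), "times must be strictly increasing")
  check_that(laser_on < laser_off, "laser_on must precede laser_off")
  n_on <- sum(times >= laser_on & times <= laser_off)
  check_that(n_on >= 20,
             "trace must contain at least 20 samples in [laser_on, laser_off] (found %d)",
             n_on)
  if (any(intensities <= 0)) {
    warning("trace '", trace_id, "' contains non-positive intensities")
  }
  structure(
    list(times = times, intensities = intensities,
         laser_on = laser_on, laser_off = laser_off,
         trace_id = trace_id, role = role, metadata = metadata),
    class = "mst_trace"
  )
}

#' @export
print.mst_trace <- function(x, ...) {
  cat(sprintf("MST trace '%s' (%s): %d samples over [%.3g, %.3g] s, laser on [%.3g, %.3g] s\n",
              x$trace_id, x$role, length(x$times), min(x$times), max(x$times),
              x$laser_on, x$laser_off))
  invisible(x)
}

# Laser-on window with time re-zeroed at laser_on.
fit_window <- function(trace) {
  sel <- trace$times >= trace$laser_on & trace$times <= trace$laser_off
  list(t = trace$times[sel] - trace$laser_on, y = trace$intensities[sel])
}

#' Stage 1: fit the free-fluorophore decay
#'
#' Nonlinear least squares of `intensity = B + C exp(k t)` over the laser-on
#' window (time re-zeroed at laser-on), with endpoint-heuristic starting
#' values: B from the tail mean, C from head minus tail, k from a log-ratio
#' estimate. A constant trace (C indistinguishable from 0) is returned as the
#' degenerate fit B = mean, C = 0, k = NA with flag `"k-unidentifiable"`.
#'
#' @param trace An [mst_trace()] with role `"fluorophore"`.
#' @return Object of class `fluorophore_fit` with `background_B`,
#'   `amplitude_C`, `decay_rate_k` (1/s, signed), `sse`, standard errors,
#'   `converged`, and `flags`.
#' @export
fit_fluorophore <- function(trace) {
  check_that(inherits(trace, "mst_trace"), "trace must be an mst_trace")
  check_that(trace$role == "fluorophore",
             "fit_fluorophore expects a fluorophore trace (got role '%s')", trace$role)
  w <- fit_window(trace)
  t <- w$t; y <- w$y
  n <- length(t)
  nh <- max(3L, n %/% 10)
  B0 <- mean(y[(n - nh + 1L):n])
  C0 <- mean(y[1:nh]) - B0
  scale <- max(abs(y)) - min(abs(y))
  if (abs(C0) <= max(1e-12 * max(abs(y), 1), 2 * stats::sd(diff(y)) / sqrt(nh))
      && stats::sd(y) < 1e-8 * max(abs(y), 1)) {
    return(structure(
      list(background_B = mean(y), amplitude_C = 0, decay_rate_k = NA_real_,
           sse = sum((y - mean(y))^2), se = c(B = NA, C = NA, k = NA),
           converged = TRUE, flags = "k-unidentifiable",
           window = w),
      class = "fluorophore_fit"))
  }
  # log-ratio slope estimate for k from head/mid amplitudes above background
  mid <- max(nh + 1L, n %/% 2)
  a1 <- mean(y[1:nh]) - B0
  a2 <- mean(y[(mid - nh %/% 2):(mid + nh %/% 2)]) - B0
  k0 <- if (is.finite(a1) && is.finite(a2) && a1 * a2 > 0) {
    log(a2 / a1) / (mean(t[(mid - nh %/% 2):(mid + nh %/% 2)]) - mean(t[1:nh]))
  } else {
    -1 / (t[n] - t[1])
  }
  if (!is.finite(k0) || k0 == 0) k0 <- -0.1
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ B + C * exp(k * t), data = df,
                      start = list(B = B0, C = C0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop_soret("fluorophore fit failed to converge: %s (start: B=%.4g C=%.4g k=%.4g)",
               conditionMessage(fit), B0, C0, k0)
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  flags <- character()
  if (abs(est[["C"]]) < 1e-7 * max(abs(y), 1)) flags <- c(flags, "k-unidentifiable")
  structure(
    list(background_B = est[["B"]], amplitude_C = est[["C"]],
         decay_rate_k = est[["k"]],
         sse = sum(stats::residuals(fit)^2),
         se = stats::setNames(se, c("B", "C", "k")),
         converged = fit$convInfo$isConv, flags = flags, window = w),
    class = "fluorophore_fit"
  )
}

#' @export
print.fluorophore_fit <- function(x, ...) {
  cat(sprintf("Fluorophore decay fit: B = %.4g, C = %.4g, k = %.4g 1/s (SSE %.4g)\n",
              x$background_B, x$amplitude_C, x$decay_rate_k, x$sse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Closed-form least squares of y ~ d0 + e0 * m: 2x2 normal equations.
lsq2 <- function(m, y) {
  n <- length(y)
  sm <- sum(m); smm <- sum(m * m); sy <- sum(y); smy <- sum(m * y)
  det <- n * smm - sm * sm
  if (abs(det) < 1e-300) return(list(d0 = mean(y), e0 = 0, sse = sum((y - mean(y))^2)))
  d0 <- (smm * sy - sm * smy) / det
  e0 <- (n * smy - sm * sy) / det
  r <- y - d0 - e0 * m
  list(d0 = d0, e0 = e0, sse = sum(r * r))
}

# Resample a library row / curve values onto window times by linear interpolation.
resample_curve <- function(curve_times, curve_values, t) {
  check_that(min(t) >= min(curve_times) - 1e-9 &&
               max(t) <= max(curve_times) + 1e-9,
             "trace window [%.4g, %.4g] s extends beyond the library time base [%.4g, %.4g] s",
             min(t), max(t), min(curve_times), max(curve_times))
  stats::approx(curve_times, curve_values, xout = t, rule = 2)$y
}

#' Stage 2: fit a particle trace against the Conc(t) library
#'
#' For every library S_T the model `d0 + e0 exp(k t) Conc_ST(t)` is linear in
#' `(d0, e0)`, so each grid point is solved in closed form and the full SSE
#' profile over S_T is retained. The minimum is refined on a 5x finer local
#' grid (interpolated curves) and polished by a parabola through the three
#' lowest points. The decay rate `k` is carried over from stage 1 and never
#' refit.
#'
#' @param trace An [mst_trace()] with role `"particle"`.
#' @param decay_rate_k Fluorophore decay rate from stage 1, 1/s (signed).
#' @param library A `conc_library`.
#' @return Object of class `particle_fit`: `background_d0`, `amplitude_e0`,
#'   `soret_ST` (1/K), `sse`, the coarse `sse_profile` (data.frame), the
#'   refinement details, and `flags` (possibly `"range-limited"` when the
#'   minimum sits on the library boundary, or `"weakly-identified"` when the
#'   best-fit depletion is below the noise floor - the regime where the
#'   fluorophore decay dominates and S_T is poorly constrained).
#' @export
fit_particle_trace <- function(trace, decay_rate_k, library) {
  check_that(inherits(trace, "mst_trace"), "trace must be an mst_trace")
  check_that(trace$role == "particle",
             "fit_particle_trace expects a particle trace (got role '%s')", trace$role)
  check_that(is.finite(decay_rate_k), "decay_rate_k must be finite (carry it over from stage 1)")
  check_that(inherits(library, "conc_library"), "library must be a conc_library")
  w <- fit_window(trace)
  t <- w$t; y <- w$y
  decay <- exp(decay_rate_k * t)

  sse_at <- function(s_val) {
    conc <- resample_curve(library$times,
                           interpolate_conc_curve(library, s_val)$values, t)
    lsq2(decay * conc, y)
  }
  # coarse pass over the library grid (exact rows, no interpolation)
  sse_grid <- vapply(seq_along(library$soret), function(k) {
    conc <- resample_curve(library$times, library$values[k, ], t)
    lsq2(decay * conc, y)$sse
  }, 0)
  imin <- which.min(sse_grid)
  flags <- character()
  if (imin == 1L || imin == length(library$soret)) {
    flags <- c(flags, "range-limited")
  }
  # local refinement: 5x finer grid across the bracketing interval
  lo <- library$soret[max(imin - 1L, 1L)]
  hi <- library$soret[min(imin + 1L, length(library$soret))]
  fine <- seq(lo, hi, length.out = 11L)
  sse_fine <- vapply(fine, function(s) sse_at(s)$sse, 0)
  jmin <- which.min(sse_fine)
  # parabola through the minimum and its neighbours
  if (jmin > 1L && jmin < length(fine)) {
    s3 <- fine[(jmin - 1L):(jmin + 1L)]
    f3 <- sse_fine[(jmin - 1L):(jmin + 1L)]
    denom <- (f3[1] - 2 * f3[2] + f3[3])
    s_hat <- if (denom > 0) {
      s3[2] + 0.5 * (s3[2] - s3[1]) * (f3[1] - f3[3]) / denom
    } else s3[2]
    s_hat <- min(max(s_hat, s3[1]), s3[3])
  } else {
    s_hat <- fine[jmin]
  }
  best <- sse_at(s_hat)
  conc_hat <- resample_curve(library$times,
                             interpolate_conc_curve(library, s_hat)$values, t)
  depth <- max(abs(conc_hat - 1))   # depletion or enrichment amplitude
  rel_noise <- if (length(t) > 2 && abs(best$e0) > 0) {
    sqrt(best$sse / (length(t) - 2)) / abs(best$e0)
  } else Inf
  if (depth < max(3 * rel_noise, 1e-5)) {
    flags <- c(flags, "weakly-identified")
  }
  structure(
    list(background_d0 = best$d0, amplitude_e0 = best$e0, soret_ST = s_hat,
         sse = best$sse,
         sse_profile = data.frame(soret = library$soret, sse = sse_grid),
         refinement = list(fine = fine, sse = sse_fine),
         decay_rate_k = decay_rate_k, flags = flags, window = w),
    class = "particle_fit"
  )
}

#' @export
print.particle_fit <- function(x, ...) {
  cat(sprintf("Particle trace fit: S_T = %.4g 1/K (d0 = %.4g, e0 = %.4g, SSE %.4g)\n",
              x$soret_ST, x$background_d0, x$amplitude_e0, x$sse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the Soret coefficient from replicate MST traces
#'
#' Full two-stage pipeline: stage-1 fits on every fluorophore trace, the
#' mean decay rate carried into stage-2 fits of every particle trace, and
#' the replicate mean and sample standard deviation (n - 1 denominator) of
#' the recovered S_T.
#'
#' @param fluorophore_traces List of fluorophore [mst_trace()]s (>= 1).
#' @param particle_traces List of particle [mst_trace()]s (>= 1).
#' @param library A `conc_library`.
#' @return Object of class `soret_result`: `mean_ST`, `sd_ST`, `n`,
#'   `decay_rate_k`, per-replicate `particle_fits`, `fluorophore_fits`, and
#'   aggregate `flags`.
#' @export
extract_soret <- function(fluorophore_traces, particle_traces, library) {
  if (inherits(fluorophore_traces, "mst_trace")) fluorophore_traces <- list(fluorophore_traces)
  if (inherits(particle_traces, "mst_trace")) particle_traces <- list(particle_traces)
  check_that(length(fluorophore_traces) >= 1, "need at least one fluorophore trace")
  check_that(length(particle_traces) >= 1, "need at least one particle trace")
  ffits <- lapply(fluorophore_traces, fit_fluorophore)
  ks <- vapply(ffits, function(f) f$decay_rate_k, 0)
  check_that(any(is.finite(ks)),
             "no fluorophore fit yielded an identifiable decay rate")
  k_bar <- mean(ks[is.finite(ks)])
  pfits <- lapply(particle_traces, fit_particle_trace,
                  decay_rate_k = k_bar, library = library)
  st <- vapply(pfits, function(f) f$soret_ST, 0)
  n <- length(st)
  flags <- character()
  if (all(vapply(pfits, function(f) length(f$flags) > 0, TRUE))) {
    flags <- c(flags, "all-replicates-flagged")
  }
  structure(
    list(mean_ST = mean(st), sd_ST = if (n > 1) stats::sd(st) else 0,
         n = n, decay_rate_k = k_bar,
         particle_fits = pfits, fluorophore_fits = ffits, flags = flags),
    class = "soret_result"
  )
}

#' @export
print.soret_result <- function(x, ...) {
  cat(sprintf("Soret extraction: S_T = %.4g +/- %.4g 1/K (n = %d; fluorophore k = %.4g 1/s)\n",
              x$mean_ST, x$sd_ST, x$n, x$decay_rate_k))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate Soret extraction results across conditions
#'
#' Produces the standard validation-table layout: one row per condition with
#' the sample label, the literature S_T (if known), and the predicted
#' mean +/- SD with n and flags.
#'
#' @param results Named list of `soret_result` objects (names = condition
#'   labels, e.g. particle sizes).
#' @param literature_ST Optional numeric vector of literature values, 1/K,
#'   recycled against `results` by name or position.
#' @return A data.frame with columns `condition`, `literature_ST_per_K`,
#'   `n`, `mean_ST_per_K`, `sd_ST_per_K`, `flags`.
#' @export
soret_report <- function(results, literature_ST = NULL) {
  check_that(length(results) >= 1, "results must contain at least one soret_result")
  labs <- names(results)
  if (is.null(labs)) labs <- sprintf("condition_%d", seq_along(results))
  lit <- rep(NA_real_, length(results))
  if (!is.null(literature_ST)) {
    if (!is.null(names(literature_ST))) {
      lit <- unname(literature_ST[labs])
    } else {
      lit[seq_along(literature_ST)] <- literature_ST
    }
  }
  data.frame(
    condition = labs,
    literature_ST_per_K = lit,
    n = vapply(results, function(r) r$n, 0L),
    mean_ST_per_K = vapply(results, function(r) r$mean_ST, 0),
    sd_ST_per_K = vapply(results, function(r) r$sd_ST, 0),
    flags = vapply(results, function(r) paste(r$flags, collapse = ";"), ""),
    row.names = NULL
  )
}

#' Quality control: detect aggregation spikes ("bumpiness")
#'
#' Sudden jumps in an MST trace indicate an aggregate passing through the
#' detection region. The trace is detrended with a rolling median; residuals
#' are standardized by their MAD and samples with |z| above `threshold`
#' count as spikes. A one-window guard band around laser-on/off is excluded,
#' since the trace has genuine kinks at the switching events.
#'
#' @param trace An [mst_trace()] (any role).
#' @param threshold z-score threshold for a spike (default 5).
#' @param window Rolling-median window (odd integer, samples).
#' @return Object of class `qc_report`: `spike_count`, `spike_times`,
#'   `max_z`, and `verdict` (`"pass"` or `"flag"`).
#' @export
qc_bumpiness <- function(trace, threshold = 5, window = 11) {
  check_that(inherits(trace, "mst_trace"), "trace must be an mst_trace")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(trace$times)
  check_that(n >= 2L * window,
             "trace too short for QC: %d samples < 2 x window (%d)", n, 2L * window)
  y <- trace$intensities
  med <- stats::runmed(y, window, endrule = "median")
  res <- y - med
  scale <- max(stats::mad(res), 1e-9 * max(abs(y), 1))
  z <- res / scale
  dt_med <- stats::median(diff(trace$times))
  guard <- window * dt_med
  in_guard <- (abs(trace$times - trace$laser_on) <= guard) |
    (abs(trace$times - trace$laser_off) <= guard)
  spikes <- which(abs(z) > threshold & !in_guard)
  structure(
    list(spike_count = length(spikes),
         spike_times = trace$times[spikes],
         max_z = max(abs(z[!in_guard])),
         threshold = threshold,
         verdict = if (length(spikes) > 0) "flag" else "pass"),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC bumpiness: %d spike(s), max |z| = %.3g (threshold %.3g) -> %s\n",
              x$spike_count, x$max_z, x$threshold, x$verdict))
  invisible(x)
}
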