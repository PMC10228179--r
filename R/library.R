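# Library of simulated Conc(t) curves indexed by the Soret coefficient, with
# provenance-hashed caching, monotone interpolation in S_T, and a CSV
# round-trip representation.

#' Build a library of simulated Conc(t) curves
#'
#' Runs the drift-diffusion solver once per Soret-coefficient grid point and
#' reduces each run to the normalized probe curve. The result is the lookup
#' table the particle-trace fit searches over. A provenance hash of all
#' solver settings allows safe reuse through an optional on-disk cache.
#'
#' @param soret_grid Sorted, strictly increasing S_T values, 1/K.
#' @param params A [transport_params()] (its `soret_ST` is ignored; one run
#'   per grid value is performed).
#' @param temperature A `temperature_series` covering `times`.
#' @param grid The shared `fv_grid`.
#' @param region A [probe_region()]; the default 2-D focal circle is the
#'   standard fitting observable.
#' @param times Output times for the curves, s (laser-on at `times[1]`).
#' @param cache_dir Optional directory for a binary cache keyed by the
#'   provenance hash; on a hit the library is loaded instead of rebuilt
#'   (with a message). A corrupt or mismatched cache file triggers a rebuild
#'   with a warning, never silent reuse.
#' @param quiet Suppress per-run progress messages.
#' @return Object of class `conc_library`: `soret`, `times`, a
#'   `length(soret)` x `length(times)` matrix `values`, and `provenance`.
#' @export
build_conc_library <- function(soret_grid, params = transport_params(),
                               temperature, grid,
                               region = probe_region("circle"),
                               times = seq(0, 20, by = 0.1),
                               cache_dir = NULL, quiet = TRUE) {
  check_that(all(diff(soret_grid) > 0), "soret_grid must be strictly increasing")
  check_that(inherits(region, "probe_region"), "region must be a probe_region")
  provenance <- hash_object(list(
    soret_grid = soret_grid, D = params$diffusion_D,
    c0 = params$initial_concentration,
    r = grid$r, z = grid$z,
    temp_times = temperature$times, steady = as.vector(temperature$steady),
    region = unclass(region), times = times,
    scheme = "fv-sg-backward-euler-1"
  ))
  cache_file <- if (!is.null(cache_dir)) {
    file.path(cache_dir, paste0("conclib-", provenance, ".rds"))
  }
  if (!is.null(cache_file) && file.exists(cache_file)) {
    lib <- tryCatch(readRDS(cache_file), error = function(e) NULL)
    if (!is.null(lib) && identical(lib$provenance, provenance)) {
      message("conc library cache hit: ", basename(cache_file))
      return(lib)
    }
    warning("conc library cache file exists but does not match its provenance; rebuilding")
  }
  values <- matrix(NA_real_, length(soret_grid), length(times))
  for (k in seq_along(soret_grid)) {
    if (!quiet) message(sprintf("  solving S_T = %+.4g 1/K (%d/%d)",
                                soret_grid[k], k, length(soret_grid)))
    p_k <- transport_params(params$diffusion_D, soret_grid[k],
                            params$initial_concentration)
    cs <- solve_drift_diffusion(p_k, temperature, grid, times)
    values[k, ] <- reduce_to_conc_curve(cs, region)$values
  }
  lib <- structure(
    list(soret = soret_grid, times = times, values = values,
         region = region, diffusion_D = params$diffusion_D,
         provenance = provenance),
    class = "conc_library"
  )
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
    saveRDS(lib, cache_file)
  }
  lib
}

#' @export
print.conc_library <- function(x, ...) {
  cat(sprintf("Conc(t) library: %d S_T values in [%.4g, %.4g] 1/K, %d times over [%.3g, %.3g] s\n",
              length(x$soret), min(x$soret), max(x$soret),
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  probe: %s, %.3g m diameter; depletion depth range [%.3g, %.3g]\n",
              x$region$kind, x$region$planar_diameter,
              min(1 - apply(x$values, 1, min)), max(1 - apply(x$values, 1, min))))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Interpolate a Conc(t) curve at an off-grid Soret coefficient
#'
#' Pointwise (per time sample) interpolation across the library's S_T grid
#' using monotone Hermite splines, so the interpolated curve always lies
#' between its bracketing library curves and is exact at grid points.
#'
#' @param library A `conc_library`.
#' @param soret Query S_T, 1/K; must lie within the library range
#'   (extrapolation is refused).
#' @return A `conc_curve`.
#' @export
interpolate_conc_curve <- function(library, soret) {
  check_that(inherits(library, "conc_library"), "library must be a conc_library")
  s <- library$soret
  if (soret < s[1] - 1e-15 || soret > s[length(s)] + 1e-15) {
    stop_soret("S_T = %.4g 1/K is outside the library range [%.4g, %.4g]; extend the library grid",
               soret, s[1], s[length(s)])
  }
  hit <- which(abs(s - soret) < 1e-14)
  if (length(hit)) {
    return(conc_curve(library$times, library$values[hit[1], ],
                      soret = s[hit[1]], region = library$region))
  }
  vals <- if (length(s) == 2) {
    w <- (soret - s[1]) / (s[2] - s[1])
    (1 - w) * library$values[1, ] + w * library$values[2, ]
  } else {
    vapply(seq_along(library$times), function(t) {
      stats::splinefun(s, library$values[, t], method = "monoH.FC")(soret)
    }, 0)
  }
  conc_curve(library$times, vals / vals[1], soret = soret, region = library$region)
}

#' Export a Conc(t) library to CSV
#'
#' Plain-text representation: a `time_s` column plus one column per library
#' S_T value (named `ST_<value>`), with the provenance hash in a comment
#' header line.
#'
#' @param library A `conc_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_library_csv <- function(library, path) {
  df <- data.frame(time_s = library$times, t(library$values),
                   check.names = FALSE)
  names(df)[-1] <- sprintf("ST_%.17g", library$soret)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# soretfit conc_library provenance=%s region=%s diameter_m=%.17g thickness_m=%.17g diffusion_D=%.17g",
                     library$provenance, library$region$kind,
                     library$region$planar_diameter, library$region$thickness,
                     library$diffusion_D), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a Conc(t) library from its CSV export
#'
#' @param path CSV written by [write_conc_library_csv()].
#' @return A `conc_library` (provenance restored from the header comment).
#' @export
read_conc_library_csv <- function(path) {
  header <- readLines(path, n = 1)
  check_that(startsWith(header, "# soretfit conc_library"),
             "%s is not a conc_library CSV export", path)
  meta <- strsplit(sub("^# soretfit conc_library ", "", header), " ")[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", meta), sub("=.*$", "", meta))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  soret <- as.numeric(sub("^ST_", "", names(df)[-1]))
  structure(
    list(soret = soret, times = df$time_s,
         values = t(as.matrix(df[, -1, drop = FALSE])),
         region = probe_region(meta[["region"]],
                               planar_diameter = as.numeric(meta[["diameter_m"]]),
                               thickness = as.numeric(meta[["thickness_m"]])),
         diffusion_D = as.numeric(meta[["diffusion_D"]]),
         provenance = meta[["provenance"]]),
    class = "conc_library"
  )
}
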