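# Internal helpers shared across modules.

# CODATA 2018 exact/recommended values.
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  NA_  = 6.02214076e23,     # Avogadro constant, 1/mol
  eps0 = 8.8541878128e-12   # vacuum permittivity, F/m
)

stop_soret <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_soret(fmt, ...)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded trace generation never disturbs the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Content hash of an R object, used for ConcLibrary provenance. Serializes to
# a temporary file and md5-sums it (stable across sessions for numeric data).
hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Bernoulli function B(x) = x / (e^x - 1) with a series branch near zero;
# the building block of the Scharfetter-Gummel exponential-fitting flux.
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  xs <- x[!small]
  out[!small] <- xs / expm1(xs)
  out
}
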