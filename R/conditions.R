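# Classed conditions used across the package. The CLI maps them to exit codes
# (format -> 2, convergence -> 3, domain -> 4).

gb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gohbiax_error")))
}

abort_domain <- function(msg, ...) {
  gb_stop(sprintf(msg, ...), "gohbiax_domain_error")
}

abort_format <- function(msg, ...) {
  gb_stop(sprintf(msg, ...), "gohbiax_format_error")
}

abort_range <- function(msg, ...) {
  gb_stop(sprintf(msg, ...), "gohbiax_range_error")
}

abort_convergence <- function(msg, ...) {
  gb_stop(sprintf(msg, ...), "gohbiax_convergence_error")
}

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# grams-force to Newtons
GF_TO_N <- 9.80665e-3

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) abort_domain("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) abort_domain("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
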